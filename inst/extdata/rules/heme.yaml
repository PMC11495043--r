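# Cytochrome classification evidence, version 1. Domain entries are
# matched as case-insensitive substrings of the hit's domain name (the
# printed names are CDD-style truncations, e.g. "Cytochrom", "decahem").
cytochrome_domains:
  - Cytochrom
  - nanowire_3heme
  - decahem
  - PSCyt1 superfamily
  - octaheme_Shew superfamily
  - MXAN_0977_Heme2 superfamily
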