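## Built-in protein similarity engine: affine-gap Smith-Waterman local
## alignment scored with BLOSUM62 (or a match/mismatch pair) and
## Karlin-Altschul e-values, producing 12-column similarity hits
## interchangeable with externally supplied tables.

#' Alignment scoring scheme
#'
#' Builds the scoring scheme for the local aligner: a substitution matrix
#' (default BLOSUM62, taken from the Biostrings matrices and extended to
#' the full ambiguity alphabet; letters without matrix rows score the
#' matrix minimum), affine gap penalties where a gap of length k costs
#' `gap_open + k * gap_extend`, and Karlin-Altschul parameters fixed to
#' the published gapped BLOSUM62/11/1 constants.
#'
#' @param matrix substitution matrix name (only `"BLOSUM62"` is shipped)
#'   or `NULL` when `match`/`mismatch` are given.
#' @param match,mismatch optional uniform match/mismatch scores used
#'   instead of a named matrix.
#' @param gap_open,gap_extend non-positive gap penalties.
#' @param lambda,karlin_k Karlin-Altschul statistics parameters.
#' @return object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(matrix = "BLOSUM62", match = NULL,
                           mismatch = NULL, gap_open = -11,
                           gap_extend = -1, lambda = 0.267,
                           karlin_k = 0.041) {
  stopifnot(gap_open <= 0, gap_extend <= 0, lambda > 0, karlin_k > 0)
  ab <- AA_ALPHABET
  if (!is.null(match) && !is.null(mismatch)) {
    sub <- base::matrix(mismatch, length(ab), length(ab),
                        dimnames = list(ab, ab))
    diag(sub) <- match
    name <- sprintf("match/mismatch %g/%g", match, mismatch)
  } else {
    if (!identical(matrix, "BLOSUM62")) {
      stop("usage error: only the BLOSUM62 matrix is shipped")
    }
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    bl <- e$BLOSUM62
    sub <- base::matrix(min(bl), length(ab), length(ab),
                        dimnames = list(ab, ab))
    common <- intersect(ab, rownames(bl))
    sub[common, common] <- bl[common, common]
    name <- "BLOSUM62"
  }
  structure(list(name = name, matrix = sub, gap_open = gap_open,
                 gap_extend = gap_extend, lambda = lambda,
                 karlin_k = karlin_k),
            class = "scoring_scheme")
}

encode_seq <- function(s) {
  idx <- match(strsplit(s, "")[[1]], AA_ALPHABET)
  if (anyNA(idx)) {
    stop("format error: sequence contains non-amino-acid characters")
  }
  idx
}

#' Optimal local alignment of two protein sequences
#'
#' Smith-Waterman alignment under the scheme's substitution matrix and
#' affine gap model. Traceback is deterministic (ties prefer the
#' diagonal, then the vertical, then the horizontal move). An empty
#' sequence yields score 0 with empty spans.
#'
#' @param a,b amino-acid strings (query, subject).
#' @param scheme a [scoring_scheme()].
#' @param query_id,subject_id identifiers carried into the result.
#' @return list with `score`, `bitscore`, `evalue` (computed with
#'   m = nchar(a), n = nchar(b)), 1-based inclusive spans
#'   `qstart`/`qend`/`sstart`/`send`, `alignment_length`, `matches`,
#'   `mismatches`, `gap_opens`.
#' @export
local_align <- function(a, b, scheme = scoring_scheme(),
                        query_id = "query", subject_id = "subject") {
  if (nchar(a) == 0L || nchar(b) == 0L) {
    return(list(query_id = query_id, subject_id = subject_id, score = 0,
                bitscore = bit_score(0, scheme),
                evalue = if (nchar(a) && nchar(b))
                  estimate_evalue(0, nchar(a), nchar(b), scheme) else NA,
                qstart = NA_integer_, qend = NA_integer_,
                sstart = NA_integer_, send = NA_integer_,
                alignment_length = 0L, matches = 0L, mismatches = 0L,
                gap_opens = 0L))
  }
  r <- sw_align_cpp(encode_seq(a), encode_seq(b), scheme$matrix,
                    scheme$gap_open, scheme$gap_extend)
  c(list(query_id = query_id, subject_id = subject_id), r,
    list(bitscore = bit_score(r$score, scheme),
         evalue = estimate_evalue(r$score, nchar(a), nchar(b), scheme)))
}

bit_score <- function(score, scheme) {
  (scheme$lambda * score - log(scheme$karlin_k)) / log(2)
}

#' Karlin-Altschul e-value
#'
#' `E = K * m * n * exp(-lambda * score)`: the expected number of local
#' alignments of at least this score between a query of length `m` and a
#' database of `n` residues. Monotonically decreasing in the score and
#' linear in both lengths.
#'
#' @param score raw alignment score (>= 0).
#' @param m query length in residues.
#' @param n database size in residues.
#' @param scheme a [scoring_scheme()] supplying lambda and K.
#' @return the e-value.
#' @export
estimate_evalue <- function(score, m, n, scheme = scoring_scheme()) {
  if (m <= 0 || n <= 0) {
    stop("usage error: query length and database size must be positive")
  }
  stopifnot(score >= 0)
  scheme$karlin_k * m * n * exp(-scheme$lambda * score)
}

#' All-vs-all similarity search
#'
#' Aligns every query against every database record and reports the pairs
#' whose Karlin-Altschul e-value (computed against the total database
#' residue count) passes the cutoff, as 12-column similarity hits sorted
#' by query id then ascending e-value. The search is exhaustive: no
#' heuristic prefilter skips pairs.
#'
#' @param queries,db protein data.frames (`protein_id`, `sequence`).
#' @param evalue_cutoff report hits with `E <= evalue_cutoff`.
#' @param scheme a [scoring_scheme()].
#' @return data.frame in the layout of `read_table("similarity", ...)`.
#' @export
search_similar <- function(queries, db, evalue_cutoff = 1e-5,
                           scheme = scoring_scheme()) {
  if (is.null(db) || nrow(db) == 0L) {
    stop("usage error: empty search database")
  }
  n_db <- sum(nchar(db$sequence))
  db_enc <- lapply(db$sequence, encode_seq)
  rows <- vector("list", nrow(queries) * nrow(db))
  k <- 0L
  for (qi in seq_len(nrow(queries))) {
    qenc <- encode_seq(queries$sequence[qi])
    m <- length(qenc)
    for (di in seq_len(nrow(db))) {
      r <- sw_align_cpp(qenc, db_enc[[di]], scheme$matrix,
                        scheme$gap_open, scheme$gap_extend)
      e <- estimate_evalue(r$score, m, n_db, scheme)
      if (e <= evalue_cutoff) {
        k <- k + 1L
        rows[[k]] <- data.frame(
          query_id = queries$protein_id[qi],
          subject_id = db$protein_id[di],
          percent_identity =
            if (r$alignment_length > 0)
              100 * r$matches / r$alignment_length else 0,
          alignment_length = r$alignment_length,
          mismatches = r$mismatches,
          gap_opens = r$gap_opens,
          qstart = r$qstart, qend = r$qend,
          sstart = r$sstart, send = r$send,
          evalue = e, bitscore = bit_score(r$score, scheme),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (k == 0L) {
    return(read_table_empty("similarity"))
  }
  out <- do.call(rbind, rows[seq_len(k)])
  out <- out[order(out$query_id, out$evalue), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## Empty, correctly typed table of a given kind.
read_table_empty <- function(kind) {
  tmp <- tempfile()
  writeLines("# empty", tmp)
  on.exit(unlink(tmp))
  read_table(kind, tmp)
}
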