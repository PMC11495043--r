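# Independent oracles used to cross-check the implementation. Each is
# written from the definition of the quantity, not by calling the code
# path it checks.

# Sliding-window CxxCH scan: test every 5-residue window with a literal
# regular expression (anchors C/C/H, wildcards any character).
heme_oracle <- function(sequence) {
  L <- nchar(sequence)
  if (L < 5) return(integer(0))
  wins <- substring(sequence, 1:(L - 4), 5:L)
  which(grepl("^C..CH$", wins))
}

# Score-only affine-gap local-alignment dynamic programme in plain R
# (gap of length k costs gap_open + k * gap_extend).
sw_oracle <- function(a, b, scheme = scoring_scheme()) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A)
  m <- length(B)
  if (n == 0 || m == 0) return(0)
  S <- scheme$matrix
  go <- scheme$gap_open
  ge <- scheme$gap_extend
  M <- matrix(0, n + 1, m + 1)
  X <- matrix(-Inf, n + 1, m + 1)
  Y <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in seq_len(n) + 1) {
    for (j in seq_len(m) + 1) {
      s <- S[A[i - 1], B[j - 1]]
      M[i, j] <- s + max(0, M[i - 1, j - 1], X[i - 1, j - 1],
                         Y[i - 1, j - 1])
      X[i, j] <- max(M[i - 1, j] + go + ge, X[i - 1, j] + ge)
      Y[i, j] <- max(M[i, j - 1] + go + ge, Y[i, j - 1] + ge)
      if (M[i, j] > best) best <- M[i, j]
    }
  }
  best
}

# Domain-filtered closure of a planted hit graph by graph reachability:
# accepted nodes are the domain-positive proteins reachable from a seed
# through domain-positive intermediates along query->subject hit edges
# (each hop is one expansion round). Uses igraph shortest paths, an
# entirely different mechanism from the round-based loop it checks.
closure_oracle <- function(seed_ids, hits, domain_pos, cutoff,
                           max_rounds = pipeline_config()$max_expansion_iterations) {
  hits <- hits[hits$evalue <= cutoff, , drop = FALSE]
  nodes <- unique(c(seed_ids, domain_pos,
                    hits$query_id, hits$subject_id))
  ok <- c(seed_ids, domain_pos)  # only these may propagate/accept
  edges <- hits[hits$subject_id %in% ok & hits$query_id %in% domain_pos,
                c("subject_id", "query_id")]
  g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                     vertices = data.frame(name = nodes))
  d <- igraph::distances(g, v = seed_ids, mode = "out")
  dmin <- apply(d, 2, min)
  acc <- names(dmin)[is.finite(dmin) & dmin > 0 &
                       dmin <= max_rounds &
                       names(dmin) %in% domain_pos]
  data.frame(protein_id = acc,
             round = as.integer(dmin[acc]),
             stringsAsFactors = FALSE)
}

# Brute-force agglomerative average linkage: clusters merge at the mean
# pairwise distance between their members; ties by lowest index pair.
avg_linkage_oracle <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA)
    best_d <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        d <- mean(D[clusters[[i]], clusters[[j]]])
        if (d < best_d) {
          best_d <- d
          best <- c(i, j)
        }
      }
    }
    heights <- c(heights, best_d)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}

# Closed-form Pearson correlation with the t-based two-sided p-value.
pearson_oracle <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(t), n - 2))
}

# Small hand-built cohort inputs for compartment tests.
mini_locations <- function(ids, labels, scores = NULL) {
  if (is.null(scores)) scores <- rep(9, length(ids))
  data.frame(protein_id = ids, raw_location = labels,
             score = scores, location = normalize_location(labels),
             stringsAsFactors = FALSE)
}

mini_sp <- function(protein_id, method, has_sp) {
  data.frame(protein_id = protein_id, method = method, has_sp = has_sp,
             sp_type = ifelse(has_sp, "SEC", "NONE"),
             stringsAsFactors = FALSE)
}

empty_sp <- function() mini_sp(character(0), character(0), logical(0))
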