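# Independent brute-force oracles, deliberately naive: full correlation
# matrices, exhaustive flood fill, hand-written step-up rule. They share no
# code path with the package implementations they check.

oracle_corr_matrix <- function(b) {
  d <- dim(b$data)
  Y <- t(matrix(b$data, prod(d[1:3]), d[4])[which(b$mask), , drop = FALSE])
  suppressWarnings(cor(Y))
}

# lFCD by exhaustive flood fill with a precomputed full correlation to v
oracle_lfcd <- function(b, r_thr = 0.6, scheme = 26, self_inclusive = TRUE) {
  R <- oracle_corr_matrix(b)
  R[is.na(R)] <- 0
  coords <- which(b$mask, arr.ind = TRUE)
  shape <- dim(b$data)[1:3]
  n <- nrow(coords)
  counts <- integer(n)
  for (v in seq_len(n)) {
    admitted <- R[v, ] >= r_thr
    admitted[v] <- TRUE
    members <- v
    repeat {
      added <- FALSE
      for (u in seq_len(n)) {
        if (u %in% members || !admitted[u]) next
        # adjacent to any current member?
        for (w in members) {
          dd <- abs(coords[u, ] - coords[w, ])
          adj <- switch(as.character(scheme),
            "6"  = sum(dd) == 1,
            "18" = max(dd) == 1 && sum(dd) <= 2,
            "26" = max(dd) == 1)
          if (adj) { members <- c(members, u); added <- TRUE; break }
        }
      }
      if (!added) break
    }
    counts[v] <- length(members) - if (self_inclusive) 0L else 1L
  }
  out <- array(NA_integer_, shape)
  out[coords] <- counts
  out
}

# gFCD by the O(N^2) pairwise rule
oracle_gfcd <- function(b, r_thr = 0.6, include_self = FALSE) {
  R <- oracle_corr_matrix(b)
  R[is.na(R)] <- 0  # zero-variance convention: r = 0, self included
  n <- nrow(R)
  counts <- integer(n)
  for (v in seq_len(n)) {
    hits <- which(R[v, ] >= r_thr)
    if (!include_self) hits <- setdiff(hits, v)
    counts[v] <- length(hits)
  }
  out <- array(NA_integer_, dim(b$data)[1:3])
  out[which(b$mask)] <- counts
  out
}

# Benjamini-Hochberg step-up, written straight from the definition
oracle_bh <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  k <- which(ps <= q * seq_len(m) / m)
  rej <- logical(m)
  if (length(k)) rej[ord[seq_len(max(k))]] <- TRUE
  rej
}

# small random bold_series for property tests
random_bold <- function(shape, n_t, seed, mask_frac = 1) {
  withr::with_seed(seed, {
    mask <- array(runif(prod(shape)) <= mask_frac, shape)
    if (!any(mask)) mask[1] <- TRUE
    bold_series(array(rnorm(prod(shape) * n_t), c(shape, n_t)),
                tr_ms = 900, mask = mask)
  })
}

# shared small anatomy/session for expensive fixtures
tiny_anatomy <- function(seed = 1, ...) {
  make_phantom_anatomy(shape = c(12, 12, 6), n_rois = 4, seed = seed, ...)
}
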