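# Independent oracles, implemented separately from the package internals.

# Needleman-Wunsch affine-gap score by straightforward R dynamic
# programming (gap run of length L costs open + L * ext).
nw_score_oracle <- function(a, b, S, open = 11, ext = 1) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  E <- matrix(NEG, n + 1, m + 1)
  F <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in seq_len(n)) E[i + 1, 1] <- -(open + i * ext)
  for (j in seq_len(m)) F[1, j + 1] <- -(open + j * ext)
  for (i in seq_len(n) + 1) {
    for (j in seq_len(m) + 1) {
      M[i, j] <- S[av[i - 1], bv[j - 1]] +
        max(M[i - 1, j - 1], E[i - 1, j - 1], F[i - 1, j - 1])
      E[i, j] <- max(M[i - 1, j] - open - ext, E[i - 1, j] - ext,
                     F[i - 1, j] - open - ext)
      F[i, j] <- max(M[i, j - 1] - open - ext, E[i, j - 1] - open - ext,
                     F[i, j - 1] - ext)
    }
  }
  max(M[n + 1, m + 1], E[n + 1, m + 1], F[n + 1, m + 1])
}

# Pattern matching oracle: for every wildcard-length assignment build a
# fixed-length regular expression and slide it over every start.
match_oracle <- function(p, seq) {
  p <- parse_motif(p)
  toks <- p$tokens
  iswild <- vapply(toks, function(t) t$type == "wild", logical(1))
  combos <- if (any(iswild))
    expand.grid(lapply(toks[iswild], function(t) t$min:t$max))
  else data.frame(row.names = 1)
  hits <- NULL
  for (r in seq_len(nrow(combos))) {
    lens <- as.integer(combos[r, ])
    w <- 0L; rx <- ""; width <- 0L
    for (t in toks) {
      if (t$type == "wild") {
        w <- w + 1L
        rx <- paste0(rx, sprintf(".{%d}", lens[w]))
        width <- width + lens[w]
      } else if (t$type == "fixed") {
        rx <- paste0(rx, t$residues); width <- width + 1L
      } else {
        rx <- paste0(rx, "[", paste(t$residues, collapse = ""), "]")
        width <- width + 1L
      }
    }
    rx <- paste0("^", rx, "$")
    for (s in seq_len(max(nchar(seq) - width + 1L, 0L)))
      if (grepl(rx, substr(seq, s, s + width - 1L)))
        hits <- rbind(hits, c(s, s + width - 1L))
  }
  if (is.null(hits))
    return(data.frame(start = integer(), end = integer()))
  hits <- unique(as.data.frame(hits))
  names(hits) <- c("start", "end")
  hits <- hits[order(hits$start, hits$end), ]
  rownames(hits) <- NULL
  hits
}

# Conservation score oracle: brute-force property intersection over the
# packaged table, reimplementing the scoring definition directly.
score_oracle <- function(chars, props, floor = 0.05) {
  n <- length(chars)
  gaps <- sum(chars == "-")
  res <- chars[chars != "-"]
  if (!length(res)) return(0L)
  if (length(unique(res)) == 1 && gaps == 0) return(11L)
  freq <- table(res) / length(res)
  types <- names(freq)[freq >= floor]
  if (!length(types)) types <- names(freq)
  uniform <- 0L
  for (pr in colnames(props)) {
    vals <- props[types, pr]
    if (all(vals) || all(!vals)) uniform <- uniform + 1L
  }
  s <- min(uniform, 10L)
  if (gaps / n > 0.2) s <- s - 1L
  max(s, 0L)
}

# UPGMA oracle: naive agglomeration returning the cophenetic matrix (in
# the input distance units, i.e. twice the node height).
upgma_cophenetic_oracle <- function(d) {
  n <- nrow(d)
  members <- as.list(seq_len(n))
  D <- d
  active <- rep(TRUE, n)
  coph <- matrix(0, n, n)
  sizes <- rep(1, n)
  for (step in seq_len(n - 1)) {
    best <- Inf; bi <- bj <- NA
    idx <- which(active)
    for (i in idx) for (j in idx) {
      if (i < j && D[i, j] < best) { best <- D[i, j]; bi <- i; bj <- j }
    }
    for (a in members[[bi]]) for (b in members[[bj]]) {
      coph[a, b] <- coph[b, a] <- best
    }
    # merged cluster replaces bi
    for (k in which(active)) {
      if (k == bi || k == bj) next
      D[bi, k] <- D[k, bi] <-
        (sizes[bi] * D[bi, k] + sizes[bj] * D[bj, k]) /
        (sizes[bi] + sizes[bj])
    }
    members[[bi]] <- c(members[[bi]], members[[bj]])
    sizes[bi] <- sizes[bi] + sizes[bj]
    active[bj] <- FALSE
  }
  dimnames(coph) <- dimnames(d)
  coph
}

# random ultrametric distance matrix from a random clock-like tree
random_ultrametric <- function(n, seed) {
  set.seed(seed)
  heights <- matrix(0, n, n)
  build <- function(leaves, h) {
    if (length(leaves) == 1) return(invisible())
    split_at <- sample(seq_len(length(leaves) - 1), 1)
    left <- leaves[seq_len(split_at)]
    right <- leaves[-seq_len(split_at)]
    for (a in left) for (b in right) {
      heights[a, b] <<- h
      heights[b, a] <<- h
    }
    build(left, h * runif(1, 0.3, 0.9))
    build(right, h * runif(1, 0.3, 0.9))
  }
  build(sample(n), 1)
  d <- 2 * heights
  dimnames(d) <- list(paste0("L", seq_len(n)), paste0("L", seq_len(n)))
  d
}
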