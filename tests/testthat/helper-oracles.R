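## Independent brute-force oracles used to check the package's optimised
## implementations, plus small fixture generators. Everything here is
## deliberately written the slow, direct way.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp <- function(seq) {
  paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", seq), "")[[1L]]),
        collapse = "")
}

mutate_dna <- function(seq, n_sub, positions = NULL) {
  v <- strsplit(seq, "", fixed = TRUE)[[1L]]
  pos <- positions %||% sample(length(v), n_sub)
  for (i in pos) v[i] <- sample(setdiff(c("A", "C", "G", "T"), toupper(v[i])), 1L)
  paste(v, collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## --- symmetric DUST, one window at a time --------------------------------

oracle_dust_mask <- function(seq, window = 64L, level = 20, linker = 1L) {
  n <- nchar(seq)
  if (n < 3L) return(rep(FALSE, n))
  v <- toupper(strsplit(seq, "", fixed = TRUE)[[1L]])
  ok <- v %in% c("A", "C", "G", "T")
  tri <- rep(NA_character_, n - 2L)
  for (i in seq_len(n - 2L)) {
    if (all(ok[i:(i + 2L)])) tri[i] <- paste(v[i:(i + 2L)], collapse = "")
  }
  w <- min(window, n)
  mask <- rep(FALSE, n)
  for (ws in seq_len(n - w + 1L)) {
    tr <- tri[ws:(ws + w - 3L)]
    tr <- tr[!is.na(tr)]
    m <- length(tr)
    if (m >= 2L) {
      cc <- table(tr)
      s <- 10 * sum(cc * (cc - 1) / 2) / (m - 1)
      if (s > level) mask[ws:(ws + w - 1L)] <- TRUE
    }
  }
  ## fill unmasked gaps of length <= linker between masked intervals
  r <- rle(mask)
  if (length(r$lengths) >= 3L) {
    for (i in 2:(length(r$values) - 1L)) {
      if (!r$values[i] && r$lengths[i] <= linker &&
          r$values[i - 1L] && r$values[i + 1L]) {
        r$values[i] <- TRUE
      }
    }
  }
  inverse.rle(r)
}

masked_positions <- function(seq) {
  which(grepl("[a-z]", strsplit(seq, "", fixed = TRUE)[[1L]]))
}

## --- best gapless segment over all diagonals (Kadane per diagonal) -------

oracle_best_gapless_score <- function(sa, sb, match = 1, mismatch = -1) {
  va <- strsplit(toupper(sa), "", fixed = TRUE)[[1L]]
  best <- -Inf
  for (sb_or in c(toupper(sb), toupper(revcomp(sb)))) {
    vb <- strsplit(sb_or, "", fixed = TRUE)[[1L]]
    la <- length(va); lb <- length(vb)
    for (d in (-(lb - 1L)):(la - 1L)) {
      qa <- max(1L, 1L + d):min(la, lb + d)
      qb <- qa - d
      x <- ifelse(va[qa] == vb[qb] & va[qa] %in% c("A", "C", "G", "T"),
                  match, mismatch)
      cs <- cumsum(x)
      seg <- max(cs - cummin(c(0, cs[-length(cs)])))
      if (seg > best) best <- seg
    }
  }
  best
}

## --- threshold scan by direct predicate evaluation -----------------------

oracle_threshold <- function(counts) {
  cv <- as.numeric(counts)  # cv[i] = count of bin i - 1
  if (cv[101L] <= cv[100L]) {
    return(list(contaminated = FALSE, threshold_bin = NA_integer_,
                fallback_used = FALSE))
  }
  for (b in 99:2) {
    if (cv[b] >= cv[b + 1L] && cv[b - 1L] >= cv[b]) {
      return(list(contaminated = TRUE, threshold_bin = b,
                  fallback_used = FALSE))
    }
  }
  pop <- which(cv > 0) - 1L
  list(contaminated = TRUE, threshold_bin = max(0L, min(pop) - 1L),
       fallback_used = TRUE)
}

random_histogram <- function() {
  counts <- integer(101L)
  shape <- sample(3L, 1L)
  if (shape == 1L) {            # sparse
    bins <- sample(0:100, sample(1:8, 1L))
    counts[bins + 1L] <- sample(0:10000, length(bins), replace = TRUE)
  } else if (shape == 2L) {     # contaminated-looking: peak at 100 + mass lower
    counts[101L] <- sample(1:10000, 1L)
    lo <- sample(60:95, 1L)
    span <- lo:sample(lo:99, 1L)
    counts[span + 1L] <- sample(0:500, length(span), replace = TRUE)
  } else {                      # dense noise
    counts <- sample(0:10000, 101L, replace = TRUE)
  }
  names(counts) <- 0:100
  counts
}

## --- sliding-window hydropathy, one position at a time -------------------

oracle_kd <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
               E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
               M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
               Y = -1.3, V = 4.2, X = 0)

oracle_tmds <- function(seq, window = 19L, threshold = 1.6, min_gap = 5L,
                        min_len = 7L) {
  v <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  L <- length(v)
  h <- (window - 1L) %/% 2L
  hits <- integer()
  for (c in seq_len(L)) {
    if (c <= h || c > L - h) next
    if (mean(oracle_kd[v[(c - h):(c + h)]]) >= threshold - 1e-9) {
      hits <- c(hits, c)
    }
  }
  if (!length(hits)) return(cbind(start = integer(), end = integer()))
  brk <- which(diff(hits) > 1L)
  starts <- hits[c(1L, brk + 1L)]
  ends <- hits[c(brk, length(hits))]
  i <- 1L
  while (i < length(starts)) {
    if (starts[i + 1L] - ends[i] - 1L < min_gap) {
      ends[i] <- ends[i + 1L]
      starts <- starts[-(i + 1L)]; ends <- ends[-(i + 1L)]
    } else i <- i + 1L
  }
  keep <- ends - starts + 1L >= min_len
  cbind(start = starts[keep], end = ends[keep])
}

random_protein <- function(n, hydrophobic_bias = 0.3) {
  aa <- names(oracle_kd)[1:20]
  w <- rep(1, 20)
  w[aa %in% c("I", "L", "V", "F", "A", "M")] <- 1 + hydrophobic_bias * 20 / 6
  paste(sample(aa, n, replace = TRUE, prob = w / sum(w)), collapse = "")
}

## --- tree screen by all-bipartition evaluation ---------------------------

oracle_screen <- function(tree, query, cfg) {
  ntip <- length(tree$tip.label)
  sup <- crosspurge::tree_supports(tree)
  pp <- ape::prop.part(tree)
  cand <- list()
  ## query-side clade labels beat complement labels; among equals, a
  ## non-NA label beats NA
  for (pass in c("query_clade", "complement")) {
    for (i in seq_along(pp)) {
      if (i == 1L) next  # root clade = all tips
      clade <- tree$tip.label[pp[[i]]]
      has_query <- query %in% clade
      if ((pass == "query_clade") != has_query) next
      side <- if (has_query) clade else setdiff(tree$tip.label, clade)
      others <- sort(setdiff(side, query))
      if (!length(others) || length(others) == ntip - 1L) next
      key <- paste(others, collapse = "/")
      s <- sup[i]
      if (is.null(cand[[key]])) {
        cand[[key]] <- list(others = others, support = s)
      } else if (is.na(cand[[key]]$support) && !is.na(s)) {
        cand[[key]]$support <- s
      }
    }
  }
  sizes <- vapply(cand, function(x) length(x$others), integer(1L))
  for (j in order(sizes)) {
    s <- cand[[j]]$support
    if (is.na(s) || s <= cfg$support_threshold) next
    g <- unique(unname(cfg$group_map[cand[[j]]$others]))
    if (cfg$expected_group %in% g) return("clean")
    if (length(g) == 1L) {
      return(if (g %in% cfg$exception_groups) "exception" else "flagged")
    }
  }
  "clean"
}

## de Bruijn sequence B(4, 3): every nucleotide triplet exactly once per
## 64-cycle (FKM / Lyndon-word construction).
de_bruijn_64 <- function() {
  k <- 4L; n <- 3L
  a <- integer(k * n + 1L)
  out <- integer()
  db <- function(t, p) {
    if (t > n) {
      if (n %% p == 0L) out <<- c(out, a[2:(p + 1L)])
    } else {
      a[t + 1L] <<- a[t - p + 1L]
      db(t + 1L, p)
      js <- seq_len(k - 1L - a[t - p + 1L]) + a[t - p + 1L]
      for (j in js) {
        a[t + 1L] <<- j
        db(t + 1L, t)
      }
    }
  }
  db(1L, 1L)
  paste(c("A", "C", "G", "T")[out + 1L], collapse = "")
}
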