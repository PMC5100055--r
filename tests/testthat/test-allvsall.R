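ctg <- function(project, id, seq) {
  data.frame(project = project, contig_id = id, sequence = seq,
             length = nchar(seq), stringsAsFactors = FALSE)
}

test_that("a verbatim copy aligns full length at 100% identity", {
  set.seed(101)
  s <- random_dna(300L)
  h <- align_pair(ctg("P1", "c1", s), ctg("P2", "c2", s))
  expect_equal(nrow(h), 1L)
  expect_equal(h$pident, 100)
  expect_equal(h$aln_len, 300L)
  expect_equal(h$score, 300L)      # match = +1 over the whole contig
  expect_equal(h$strand, "+")
  expect_equal(c(h$q_start, h$q_end, h$s_start, h$s_end), c(1L, 300L, 1L, 300L))
})

test_that("three interior substitutions give pident 99 and score 294", {
  set.seed(102)
  s <- random_dna(300L)
  s2 <- mutate_dna(s, 3L, positions = c(50L, 150L, 250L))
  h <- align_pair(ctg("P1", "c1", s), ctg("P2", "c2", s2))
  expect_equal(h$score[1L], 294L)  # 297 matches - 3 mismatches
  expect_equal(h$pident[1L], 99, tolerance = 1e-9)
  expect_equal(h$score[1L], oracle_best_gapless_score(s, s2))
})

test_that("independent random contigs share no qualifying alignment", {
  set.seed(103)
  for (i in 1:100) {
    h <- align_pair(ctg("P1", "c1", random_dna(300L)),
                    ctg("P2", "c2", random_dna(300L)))
    expect_equal(nrow(h), 0L)
  }
})

test_that("reverse-complement copies are found on the minus strand", {
  set.seed(104)
  s <- random_dna(250L)
  h <- align_pair(ctg("P1", "c1", s), ctg("P2", "c2", revcomp(s)))
  expect_equal(h$strand[1L], "-")
  expect_equal(h$pident[1L], 100)
  expect_equal(h$aln_len[1L], 250L)
  expect_true(h$s_start[1L] <= h$s_end[1L])  # forward-strand coordinates
})

test_that("soft-masked copies cannot seed but masked flanks extend", {
  set.seed(105)
  s <- random_dna(300L)
  h <- align_pair(ctg("P1", "c1", tolower(s)), ctg("P2", "c2", s))
  expect_equal(nrow(h), 0L)  # no uppercase seed anywhere

  half <- paste0(tolower(substr(s, 1L, 150L)), substr(s, 151L, 300L))
  h2 <- align_pair(ctg("P1", "c1", half), ctg("P2", "c2", s))
  expect_equal(h2$aln_len[1L], 300L)  # extension runs through the mask
  expect_equal(h2$pident[1L], 100)
})

test_that("best_hits keeps the top-scoring hit per unordered pair", {
  base <- data.frame(
    q_project = "P1", q_contig = "c1", s_project = "P2", s_contig = "c9",
    pident = c(100, 95), aln_len = c(300L, 150L), mismatch = 0L,
    gapopen = 0L, q_start = 1L, q_end = 300L, s_start = 1L, s_end = 300L,
    evalue = 0, score = c(550, 300), strand = "+", stringsAsFactors = FALSE)
  out <- best_hits(base)
  expect_equal(nrow(out), 1L)
  expect_equal(out$score, 550)

  flip <- base
  flip$q_project <- "P2"; flip$q_contig <- "c1"
  flip$s_project <- "P1"; flip$s_contig <- "c9"
  flip$score <- c(400, 410)
  out2 <- best_hits(flip)
  expect_equal(nrow(out2), 1L)
  expect_equal(out2$score, 410)
  expect_equal(out2$q_project, "P1")  # canonical orientation
})

test_that("best_hits equals a group-by-max oracle on random hit sets", {
  set.seed(106)
  pairs <- data.frame(qp = sprintf("P%d", sample(1:3, 50L, TRUE)),
                      qc = sprintf("c%02d", 1:50),
                      sp = sprintf("Q%d", sample(1:3, 50L, TRUE)),
                      sc = sprintf("d%02d", 1:50), stringsAsFactors = FALSE)
  i <- sample(50L, 1000L, replace = TRUE)
  sw <- sample(c(TRUE, FALSE), 1000L, replace = TRUE)
  hits <- data.frame(
    q_project = ifelse(sw, pairs$sp[i], pairs$qp[i]),
    q_contig = ifelse(sw, pairs$sc[i], pairs$qc[i]),
    s_project = ifelse(sw, pairs$qp[i], pairs$sp[i]),
    s_contig = ifelse(sw, pairs$qc[i], pairs$sc[i]),
    pident = round(runif(1000L, 80, 100), 2), aln_len = sample(150:500, 1000L, TRUE),
    mismatch = 0L, gapopen = 0L, q_start = 1L, q_end = 1L, s_start = 1L,
    s_end = 1L, evalue = 0, score = sample(64:500, 1000L, TRUE),
    strand = "+", stringsAsFactors = FALSE)
  out <- best_hits(hits)
  key <- paste(pmin(paste(hits$q_project, hits$q_contig),
                    paste(hits$s_project, hits$s_contig)),
               pmax(paste(hits$q_project, hits$q_contig),
                    paste(hits$s_project, hits$s_contig)))
  expected_max <- tapply(hits$score, key, max)
  got <- setNames(out$score, paste(paste(out$q_project, out$q_contig),
                                   paste(out$s_project, out$s_contig)))
  expect_equal(length(got), length(expected_max))
  expect_equal(unname(got[names(expected_max)]), as.numeric(expected_max))
})

test_that("all_vs_all is deterministic, symmetric and skips within-project pairs", {
  set.seed(107)
  shared <- random_dna(400L)
  contigs <- rbind(
    ctg("P1", "c1", shared), ctg("P1", "c2", random_dna(350L)),
    ctg("P2", "c1", shared), ctg("P2", "c2", random_dna(350L)),
    ctg("P3", "c1", random_dna(300L)))
  h <- all_vs_all(contigs)
  expect_equal(nrow(h), 1L)
  expect_equal(h$q_project, "P1")
  expect_equal(h$s_project, "P2")
  expect_equal(h$pident, 100)

  hperm <- all_vs_all(contigs[sample(nrow(contigs)), ])
  expect_equal(hperm, h)

  expect_error(all_vs_all(contigs[contigs$project == "P1", ]), ">=2 projects")
})

test_that("reported scores match the all-diagonal brute-force scan", {
  set.seed(108)
  params <- align_params()
  for (i in 1:40) {
    la <- sample(80:200, 1L)
    a <- random_dna(la)
    b <- switch(1L + (i %% 4L),
                mutate_dna(a, rbinom(1L, la, 0.01)),        # near-identical
                random_dna(sample(80:200, 1L)),             # unrelated
                revcomp(mutate_dna(a, rbinom(1L, la, 0.005))),
                paste0(random_dna(40L), substr(a, 20L, la - 19L),
                       random_dna(40L)))                    # embedded segment
    h <- align_pair(ctg("P1", "c1", a), ctg("P2", "c2", b), params)
    top <- if (nrow(h)) max(h$score) else NA_integer_
    oracle <- oracle_best_gapless_score(a, b)
    if (oracle >= params$min_score) {
      expect_equal(top, oracle, info = paste("case", i))
    } else {
      expect_true(is.na(top), info = paste("case", i))
    }
    if (nrow(h)) {
      expect_true(all(h$pident > 0 & h$pident <= 100))
      expect_true(all(h$score <= h$aln_len))
    }
  }
})
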