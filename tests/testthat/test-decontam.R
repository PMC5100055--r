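test_that("hit qualification is an inclusive OR of the two length arms", {
  cfg <- decontam_config()
  expect_true(qualify_hit(160L, 1000L, 900L, cfg))   # >= 150 nt arm
  expect_true(qualify_hit(100L, 180L, 1000L, cfg))   # >= 50% of shorter arm
  expect_false(qualify_hit(100L, 250L, 1000L, cfg))  # fails both
  expect_error(qualify_hit(300L, 250L, 1000L, cfg), "corrupt")
})

test_that("identity bins use round-half-up and conserve counts", {
  h <- build_pair_histogram(c(100.0, 99.7, 99.4, 85.2), "A|B")
  expect_equal(unname(h$counts[c("100", "99", "85")]), c(2L, 1L, 1L))
  expect_equal(sum(h$counts), h$n_hits)

  set.seed(9)
  p <- runif(10000, 0, 100)
  h2 <- build_pair_histogram(p, "A|B")
  expect_equal(sum(h2$counts), 10000L)
  expect_equal(unname(h2$counts), tabulate(floor(p + 0.5) + 1L, 101L))

  h0 <- build_pair_histogram(numeric(), "A|B")
  expect_equal(h0$n_hits, 0L)
  expect_true(all(h0$counts == 0L))
})

test_that("the threshold scan reproduces the worked traces", {
  counts <- integer(101L); names(counts) <- 0:100
  counts[c("100", "99", "98", "97", "96", "95", "94")] <- c(50, 10, 8, 6, 5, 5, 7)
  th <- detect_threshold(counts)
  expect_true(th$contaminated)
  expect_equal(th$threshold_bin, 96L)
  expect_false(th$fallback_used)

  counts2 <- integer(101L)
  counts2[101L] <- 5L; counts2[100L] <- 9L
  th2 <- detect_threshold(counts2)
  expect_false(th2$contaminated)
  expect_true(is.na(th2$threshold_bin))

  counts3 <- integer(101L)
  counts3[101L] <- 50L; counts3[100L] <- 10L
  th3 <- detect_threshold(counts3)
  expect_equal(th3$threshold_bin, 98L)  # zero bins satisfy the triple at 98
})

test_that("RPKM follows its closed form", {
  expect_equal(compute_rpkm(100, 1000, 1e6), 100)
  expect_equal(compute_rpkm(0, 777, 123456), 0)
  expect_equal(compute_rpkm(123, 777, 9876543),
               1e9 * 123 / 777 / 9876543, tolerance = 1e-9)
  expect_error(compute_rpkm(10, 0, 1e6), "length")
  expect_error(compute_rpkm(10, 100, 0), "total")
})

test_that("arbitration applies the 10x and 10,000 RPKM exceptions", {
  cfg <- decontam_config()
  a <- arbitrate_pair(500, 20, cfg)     # 25x
  expect_equal(c(a$status_a, a$status_b), c("retained", "discarded"))
  expect_equal(a$reason_a, "rpkm_ratio_winner")

  b <- arbitrate_pair(12000, 11000, cfg)  # ratio < 10, both highly expressed
  expect_equal(c(b$status_a, b$status_b), c("retained", "retained"))
  expect_equal(c(b$reason_a, b$reason_b),
               rep("rpkm_high_expression", 2L))

  d <- arbitrate_pair(50, 40, cfg)
  expect_equal(c(d$status_a, d$status_b), c("discarded", "discarded"))
  expect_equal(d$reason_a, "default_both")

  z <- arbitrate_pair(5, 0, cfg)        # zero partner counts as 10x
  expect_equal(z$status_a, "retained")
  zz <- arbitrate_pair(0, 0, cfg)
  expect_equal(c(zz$status_a, zz$status_b), c("discarded", "discarded"))

  off <- arbitrate_pair(500, 20, decontam_config(arbitration = FALSE))
  expect_equal(c(off$status_a, off$status_b), c("discarded", "discarded"))
})

make_mini_world <- function(rpkm_a = 500, rpkm_b = 20, len = 1000L,
                            total = 1e6) {
  set.seed(55)
  s <- random_dna(len)
  contigs <- data.frame(
    project = c("P1", "P1", "P2", "P2"),
    contig_id = c("c1", "c2", "c1", "c2"),
    sequence = c(s, random_dna(800L), s, random_dna(700L)),
    length = c(len, 800L, len, 700L), stringsAsFactors = FALSE)
  counts <- data.frame(
    project = contigs$project, contig_id = contigs$contig_id,
    read_count = c(rpkm_a * len * total / 1e9, 10,
                   rpkm_b * len * total / 1e9, 10),
    stringsAsFactors = FALSE)
  attr(counts, "project_totals") <- c(P1 = total, P2 = total)
  list(contigs = contigs, counts = counts)
}

test_that("run_decontam flags a planted copy and arbitrates by expression", {
  w <- make_mini_world()
  hits <- all_vs_all(mask_contigs(w$contigs))
  res <- run_decontam(w$contigs, hits, w$counts)
  dec <- res$decisions
  get <- function(p, c) dec$status[dec$project == p & dec$contig_id == c]
  expect_equal(get("P1", "c1"), "retained")   # high-RPKM donor
  expect_equal(get("P2", "c1"), "discarded")  # low-RPKM copy
  expect_equal(get("P1", "c2"), "retained")
  expect_true(res$thresholds$contaminated[1L])
})

test_that("excluded same-species pairs contribute no flags", {
  w <- make_mini_world()
  hits <- all_vs_all(mask_contigs(w$contigs))
  res <- run_decontam(w$contigs, hits, w$counts,
                      decontam_config(excluded_pairs = "P1|P2"))
  expect_true(all(res$decisions$status == "retained"))
  expect_equal(nrow(res$thresholds), 0L)
})

test_that("a flagged contig without an expression record is an error", {
  w <- make_mini_world()
  hits <- all_vs_all(mask_contigs(w$contigs))
  counts <- w$counts[-1L, ]
  attr(counts, "project_totals") <- attr(w$counts, "project_totals")
  expect_error(run_decontam(w$contigs, hits, counts), "P1\\|c1")
  ## but arbitration can be disabled, discarding both members
  res <- run_decontam(w$contigs, hits, NULL,
                      decontam_config(arbitration = FALSE))
  expect_equal(sum(res$decisions$status == "discarded"), 2L)
})

test_that("raising the qualification bars never enlarges the contaminant set", {
  set.seed(77)
  sim <- simulate_projects(sim_params(n_projects = 3L,
                                      contigs_per_project = 40L), seed = 3)
  ct <- mask_contigs(sim$contigs)
  hits <- all_vs_all(ct)
  flagged_set <- function(cfg) {
    d <- run_decontam(ct, hits, sim$counts, cfg)$decisions
    paste(d$project, d$contig_id)[d$reason != "not_flagged"]
  }
  base <- flagged_set(decontam_config())
  for (cfg in list(decontam_config(min_hit_len = 300L),
                   decontam_config(min_frac_of_shorter = 0.9))) {
    expect_true(all(flagged_set(cfg) %in% base))
  }
})

test_that("decisions are independent of input row order", {
  sim <- simulate_projects(sim_params(n_projects = 3L,
                                      contigs_per_project = 40L), seed = 5)
  ct <- mask_contigs(sim$contigs)
  hits <- all_vs_all(ct)
  r1 <- run_decontam(ct, hits, sim$counts)
  set.seed(1)
  r2 <- run_decontam(ct[sample(nrow(ct)), ], hits[sample(nrow(hits)), ],
                     sim$counts)
  expect_equal(r2$decisions, r1$decisions)
  expect_equal(r2$thresholds, r1$thresholds)
})

test_that("purge partitions contigs exactly and carries proteins along", {
  contigs <- data.frame(
    project = "P1", contig_id = sprintf("c%d", 1:10),
    sequence = replicate(10, random_dna(60L)), length = 60L,
    stringsAsFactors = FALSE)
  decisions <- data.frame(
    project = "P1", contig_id = contigs$contig_id,
    status = c(rep("discarded", 3L), rep("retained", 7L)),
    reason = "default_both", evidence = "", stringsAsFactors = FALSE)
  proteins <- data.frame(
    project = "P1", protein_id = c("c1.p1", "c1.p2", "c9.p1", "zz.p1"),
    contig_id = c("c1", "c1", "c9", "zz"),
    sequence = "MSTLK", stringsAsFactors = FALSE)
  expect_warning(pp <- purge(contigs, decisions, proteins), "unknown")
  expect_equal(nrow(pp$retained_nt), 7L)
  expect_equal(nrow(pp$purged_nt), 3L)
  expect_equal(rbind(pp$purged_nt, pp$retained_nt)[order(c(1:3, 4:10)), ],
               contigs, ignore_attr = TRUE)
  expect_equal(pp$purged_aa$protein_id, c("c1.p1", "c1.p2"))
  expect_true("zz.p1" %in% pp$retained_aa$protein_id)  # fail-open orphan
  expect_equal(pp$report$n_orphan[2L], 1L)

  none <- decisions; none$status <- "retained"
  pp0 <- purge(contigs, none)
  expect_equal(nrow(pp0$purged_nt), 0L)
  expect_equal(pp0$retained_nt, contigs, ignore_attr = TRUE)
})
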