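test_that("hydropathy windows find an isolated hydrophobic stretch", {
  seq <- paste0(strrep("D", 30L), strrep("I", 25L), strrep("D", 30L))
  tmds <- predict_tmds(seq)
  expect_equal(nrow(tmds), 1L)
  expect_gte(tmds[1L, "start"], 31L)   # inside the I-stretch
  expect_lte(tmds[1L, "end"], 55L)
  expect_equal(tmds, oracle_tmds(seq))

  expect_equal(nrow(predict_tmds(strrep("G", 100L))), 0L)
  expect_warning(out <- predict_tmds("MKT"), "shorter")
  expect_equal(nrow(out), 0L)
})

test_that("ten hydrophobic stretches with hydrophilic loops give ten TMDs", {
  seq <- paste(rep(strrep("L", 21L), 10L),
               collapse = strrep("DRKE", 4L))  # 16-residue loops
  tmds <- predict_tmds(seq)
  expect_equal(nrow(tmds), 10L)
  expect_equal(tmds, oracle_tmds(seq))
})

test_that("TMD prediction equals the per-position window oracle on random proteins", {
  set.seed(21)
  for (i in 1:100) {
    seq <- random_protein(sample(30:200, 1L), hydrophobic_bias = runif(1, 0, 1))
    expect_equal(predict_tmds(seq), oracle_tmds(seq), info = paste("seq", i))
  }
})

test_that("motif scanning covers the documented variants and overlaps", {
  m <- scan_motifs("AAEGAQAA")
  expect_equal(m$class, "EGXQ")
  expect_equal(m$start, 3L)
  expect_equal(m$text, "EGAQ")

  m2 <- scan_motifs("MGRHM")
  expect_equal(m2$class[1L], "GRQ")
  expect_equal(m2$start[1L], 2L)

  m3 <- scan_motifs(paste0(strrep("A", 9L), "QAAAQ"))
  q <- m3[m3$class == "xQxxxQx", ]
  expect_equal(q$start, 10L)   # Q at 10 and 14

  ## overlapping glutamine pairs are all reported
  m4 <- scan_motifs("QAAAQAAAQ")
  expect_equal(m4$start[m4$class == "xQxxxQx"], c(1L, 5L))

  ## variants: K/M/H for Q, A for G; GQS
  expect_equal(scan_motifs("AEGAKA")$class, "EGXQ")
  expect_equal(scan_motifs("AGQSA")$class, "GRQ")
  ## case folding
  expect_equal(scan_motifs("aaegaqaa")$start, 3L)
})

test_that("motif pairs anchor on consecutive TMDs with greedy assignment", {
  tmds <- cbind(start = c(40L, 80L, 120L), end = c(60L, 100L, 140L))
  motifs <- data.frame(class = c("EGXQ", "GRQ"), start = c(75L, 121L),
                       text = c("EGAQ", "GRQ"), stringsAsFactors = FALSE)
  p <- pair_motifs(motifs, tmds)
  expect_equal(nrow(p), 1L)
  expect_equal(p$tmd_index, 2L)

  no_grq <- motifs[motifs$class == "EGXQ", ]
  expect_equal(nrow(pair_motifs(no_grq, tmds)), 0L)
})

test_that("classification follows the TMD/pair definitions in both modes", {
  fx <- make_canonical_fixtures()
  sit <- fx$sequence[fx$protein_id == "canonical_SIT"]
  sitl <- fx$sequence[fx$protein_id == "canonical_SITL"]

  for (mode in c("strict", "tolerant")) {
    cs <- classify_transporter(sit, mode = mode)
    expect_equal(cs$label, "SIT")
    expect_equal(cs$n_tmds, 10L)
    expect_equal(cs$n_pairs, 2L)
    expect_equal(cs$pairs$tmd_index, c(2L, 7L))
    cl <- classify_transporter(sitl, mode = mode)
    expect_equal(cl$label, "SIT-L")
    expect_equal(cl$n_tmds, 5L)
    expect_equal(cl$n_pairs, 1L)
  }

  expect_equal(classify_transporter(
    fx$sequence[fx$protein_id == "motifs_no_tmds"])$label, "unclassified")
  expect_equal(classify_transporter(
    fx$sequence[fx$protein_id == "tmds_no_motifs"])$label, "unclassified")
})

test_that("classification is case-insensitive and deterministic", {
  fx <- make_canonical_fixtures()
  sit <- fx$sequence[fx$protein_id == "canonical_SIT"]
  a <- classify_transporter(sit)
  b <- classify_transporter(tolower(sit))
  d <- classify_transporter(sit)
  expect_equal(b$label, a$label)
  expect_equal(b$tmds, a$tmds)
  expect_equal(d, a)
})

test_that("SIT splitting takes the TMD5/6 loop midpoint and conserves residues", {
  tmds <- cbind(start = c(1, 31, 61, 91, 191, 230, 260, 290, 320, 350),
                end = c(20, 50, 80, 110, 210, 250, 280, 310, 340, 370))
  seq <- random_protein(380L)
  sp <- split_sit(seq, tmds)
  expect_equal(sp$split_position, 220L)  # (210 + 230) %/% 2
  expect_equal(nchar(sp$n_half), 220L)
  expect_equal(paste0(sp$n_half, sp$c_half), seq)

  tmds2 <- tmds; tmds2[5L, "end"] <- 100; tmds2[6L, "start"] <- 101
  expect_equal(split_sit(seq, tmds2)$split_position, 100L)

  expect_error(split_sit(seq, tmds[1:5, ]), "6")

  set.seed(31)
  for (i in 1:20) {
    s <- random_protein(sample(250:400, 1L))
    sp2 <- split_sit(s, tmds)
    expect_equal(paste0(sp2$n_half, sp2$c_half), s)
  }
})

test_that("the canonical SIT splits into two SIT-L-like halves", {
  fx <- make_canonical_fixtures()
  sit <- fx$sequence[fx$protein_id == "canonical_SIT"]
  call <- classify_transporter(sit)
  sp <- split_sit(sit, call$tmds)
  for (half in c(sp$n_half, sp$c_half)) {
    hc <- classify_transporter(half)
    expect_equal(hc$n_tmds, 5L)
    expect_equal(hc$n_pairs, 1L)
    expect_equal(hc$label, "SIT-L")
  }
})
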