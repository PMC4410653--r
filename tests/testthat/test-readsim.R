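# read simulation: pair counts, error model, truth enumeration, sharding,
# name encoding, and the engine adapter contract

test_that("pair count follows the coverage equation and reads match the haplotypes at zero error", {
  sm <- get_smoke(coverage = 5, err = 0)
  total <- sum(nchar(sm$dip$haplotypes))
  expect_equal(length(unique(sm$reads$pair_id)), round(5 * total / (2 * 100)))
  # every read base matches its host source (mate 2 is reverse complemented)
  idx <- seq(1, nrow(sm$reads), by = 97)
  for (i in idx) {
    r <- sm$reads[i, ]
    src <- substr(sm$dip$haplotypes[[r$contig]], r$start0 + 1, r$end0)
    if (r$mate == 2L) src <- revcomp_naive(src)
    expect_identical(r$seq, src)
  }
})

test_that("error-free reads with a single full-length alternative fetch back from the reference", {
  sm <- get_smoke(coverage = 5, err = 0)
  truth <- sm$truth
  # restrict to reads not overlapping any substitution edit on their haplotype
  snvs <- truth[truth$var_type %in% c("SNV", "MNP"), ]
  checked <- 0L
  for (i in seq(1, nrow(sm$reads), by = 23)) {
    r <- sm$reads[i, ]
    a <- r$alts[[1]]
    if (length(a$anchor0) != 1L || a$alen[1] != 100L || a$label[1] != "SEQ") next
    hap_gt <- if (grepl("hapA$", r$contig)) snvs$gt1 else snvs$gt2
    touching <- snvs$pos - 1 >= a$anchor0 & snvs$pos - 1 < a$anchor0 + 100 & hap_gt == 1L
    if (any(touching)) next
    s <- substr(sm$ref[[a$ref_contig]], a$anchor0 + 1, a$anchor0 + 100)
    read_fwd <- if (r$mate == 2L) revcomp_naive(r$seq) else r$seq
    expect_identical(read_fwd, s)
    checked <- checked + 1L
  }
  expect_gt(checked, 50)
})

test_that("substitution errors appear at roughly the requested rate and never self-substitute", {
  sm0 <- get_smoke(coverage = 5, err = 0)
  p <- read_sim_params(coverage = 2, sub_error_rate = 0.01, seed = 4)
  reads <- simulate_reads(sm0$dip$haplotypes, sm0$dip$map, p)
  n_mm <- 0L; n_bases <- 0L
  for (i in seq_len(nrow(reads))) {
    r <- reads[i, ]
    src <- substr(sm0$dip$haplotypes[[r$contig]], r$start0 + 1, r$end0)
    if (r$mate == 2L) src <- revcomp_naive(src)
    mm <- sum(strsplit(r$seq, "")[[1]] != strsplit(src, "")[[1]])
    n_mm <- n_mm + mm; n_bases <- n_bases + 100L
  }
  rate <- n_mm / n_bases
  sigma <- sqrt(0.01 * 0.99 / n_bases)
  expect_lt(abs(rate - 0.01), 4 * sigma)
  # flat quality string encodes the error rate
  expect_equal(unique(reads$qual), strrep(rawToChar(as.raw(20 + 33)), 100))
})

test_that("realized depth lands within 5% of the requested coverage", {
  sm <- get_smoke(coverage = 5, err = 0)
  realized <- sum(nchar(sm$reads$seq)) / sum(nchar(sm$dip$haplotypes))
  expect_lt(abs(realized - 5) / 5, 0.05)
})

test_that("shard outputs concatenated in order are byte-identical to a single-shard run", {
  sm <- get_smoke(coverage = 5, err = 0)
  p1 <- read_sim_params(coverage = 1, sub_error_rate = 0.002, seed = 7, shards = 1)
  p4 <- read_sim_params(coverage = 1, sub_error_rate = 0.002, seed = 7, shards = 4)
  whole <- simulate_reads(sm$dip$haplotypes, sm$dip$map, p1)
  parts <- lapply(1:4, function(j) simulate_reads(sm$dip$haplotypes, sm$dip$map, p4, shard = j))
  d1 <- tempfile(); d2 <- tempfile()
  write_fastq(whole, d1)
  shard_files <- lapply(parts, function(r) { f <- tempfile(); write_fastq(r, f); f })
  for (m in 1:2) {
    single <- readLines(paste0(d1, "_", m, ".fq"))
    concat <- unlist(lapply(shard_files, function(f) readLines(paste0(f, "_", m, ".fq"))))
    expect_identical(concat, single)
  }
})

test_that("truth records round-trip through the read-name encoding", {
  sm <- get_smoke(coverage = 5, err = 0)
  idx <- seq(1, nrow(sm$reads), by = 11)
  for (i in idx) {
    r <- sm$reads[i, ]
    expect_lte(nchar(r$name), 254L)
    expect_false(grepl("[[:space:]/]", r$name))
    tr <- decode_truth(r$name)
    expect_equal(tr$read_id, r$read_id)
    expect_equal(tr$hap, r$contig)
    m <- tr$mates[[r$mate]]
    expect_identical(m$alts, r$alts[[1]])
    expect_identical(sort(m$labels), sort(strsplit(r$labels, ",")[[1]]))
  }
  # both mates of a pair share one read name (paired-end aligner contract)
  m1 <- sm$reads[sm$reads$mate == 1L, ]
  m2 <- sm$reads[sm$reads$mate == 2L, ]
  expect_identical(m1$name[order(m1$pair_id)], m2$name[order(m2$pair_id)])
})

test_that("decode distinguishes foreign reads from corrupt payloads", {
  expect_error(decode_truth("not_a_simulated_read"),
               class = "simval_not_simulated")
  expect_error(decode_truth("SRR123.456"), class = "simval_not_simulated")
  expect_error(decode_truth("vs:x0000001:!!notb64!!"),
               class = "simval_corrupt_payload")
  expect_error(decode_truth("vs:x0000001:*"),
               class = "simval_corrupt_payload")  # overflow without sidecar
})

test_that("oversized payloads fall back to the sidecar and decode through it", {
  alts <- list(ref_contig = rep("ctg_with_a_rather_long_name", 12),
               anchor0 = as.integer(1:12) * 1000L,
               strand = rep("+", 12), label = rep("SEQ", 12),
               alen = rep(50L, 12))
  mates <- list(list(labels = "SEQ", alts = alts),
                list(labels = "SEQ", alts = alts))
  enc <- encode_truth("r0000001", "ctg_with_a_rather_long_name_hapA", mates)
  expect_lte(nchar(enc$name), 254L)
  expect_false(is.na(enc$overflow))
  sidecar <- tibble::tibble(read_id = "r0000001", payload = enc$overflow)
  tr <- decode_truth(enc$name, sidecar)
  expect_equal(tr$mates[[1]]$alts$anchor0, alts$anchor0)
  expect_equal(tr$mates[[2]]$alts$anchor0, alts$anchor0)
})

test_that("reads straddling an inversion edge carry one alternative per side", {
  ref <- c(c1 = strrep("ACTGG", 600))  # 3000 bp
  v <- toy_variant("c1", 1000, "G", "<INV>", "INV", 500, id = "inv1")
  dip <- build_diploid(ref, v)
  # host interval 60 bp before the edge + 40 bp inside
  tr <- true_alignments(dip$map, "c1_hapA", 940L, 1040L)
  expect_equal(length(tr$alts$anchor0), 2L)
  expect_equal(tr$alts$strand, c("+", "-"))
  expect_equal(tr$alts$alen, c(60L, 40L))
  expect_equal(tr$alts$anchor0[1], 940L)
  # inverted segment: host [1000,1040) maps to the far end of the span
  expect_equal(tr$alts$anchor0[2], 1000L + 500L - 40L)
  # read fully inside one SEQ block: a single full-length alternative
  tr2 <- true_alignments(dip$map, "c1_hapA", 100L, 200L)
  expect_equal(length(tr2$alts$anchor0), 1L)
  expect_equal(tr2$alts$alen, 100L)
  # read fully inside a novel insertion anchors at the breakpoint
  vi <- toy_variant("c1", 1000, "G", "<INS>", "INS", 400,
                    ins_seq = strrep("TTAAC", 80), id = "insx")
  dipi <- build_diploid(ref, vi)
  tri <- true_alignments(dipi$map, "c1_hapA", 1100L, 1200L)
  expect_equal(tri$alts$label, "INS_NOVEL")
  expect_equal(tri$alts$anchor0, 1000L)
})

test_that("the built-in engine routed through the adapter equals the direct call", {
  sm <- get_smoke(coverage = 5, err = 0)
  p <- read_sim_params(coverage = 1, sub_error_rate = 0.001, seed = 3)
  direct <- simulate_reads(sm$dip$haplotypes, sm$dip$map, p)
  routed <- simulate_with_engine(simval:::builtin_read_engine,
                                 sm$dip$haplotypes, sm$dip$map, p)
  expect_identical(as.data.frame(direct[, names(direct) != "alts"]),
                   as.data.frame(routed[, names(routed) != "alts"]))
  expect_identical(direct$alts, routed$alts)
})

test_that("adapter reads with missing or out-of-range truth are rejected by name", {
  sm <- get_smoke(coverage = 5, err = 0)
  p <- read_sim_params(coverage = 0.5, sub_error_rate = 0, seed = 3)
  bad_engine <- function(haplotypes, params, shard = NULL, prefix = "r") {
    r <- simval:::builtin_read_engine(haplotypes, params, shard, prefix)
    r$start0[3] <- NA_integer_
    r
  }
  expect_error(simulate_with_engine(bad_engine, sm$dip$haplotypes, sm$dip$map, p),
               "no truth coordinates")
  oob_engine <- function(haplotypes, params, shard = NULL, prefix = "r") {
    r <- simval:::builtin_read_engine(haplotypes, params, shard, prefix)
    r$end0[5] <- nchar(haplotypes[[r$contig[5]]]) + 50L
    r
  }
  expect_error(simulate_with_engine(oob_engine, sm$dip$haplotypes, sm$dip$map, p),
               "outside host contig range")
})

test_that("shuffled engine output leaves validation results unchanged", {
  sm <- get_smoke(coverage = 5, err = 0)
  p <- read_sim_params(coverage = 1, sub_error_rate = 0, seed = 9)
  shuffled_engine <- function(haplotypes, params, shard = NULL, prefix = "r") {
    r <- simval:::builtin_read_engine(haplotypes, params, shard, prefix)
    set.seed(42)
    r[sample.int(nrow(r)), , drop = FALSE]
  }
  a <- simulate_reads(sm$dip$haplotypes, sm$dip$map, p)
  b <- simulate_with_engine(shuffled_engine, sm$dip$haplotypes, sm$dip$map, p)
  sa <- tempfile(fileext = ".sam"); sb <- tempfile(fileext = ".sam")
  write_truth_sam(a, sm$ref, sa)
  write_truth_sam(b, sm$ref, sb)
  ra <- validate_alignments(sa); rb <- validate_alignments(sb)
  expect_identical(dplyr::arrange(tidy(ra), category),
                   dplyr::arrange(tidy(rb), category))
})
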