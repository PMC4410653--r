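# variant-call comparison: matching rules, stratification, degenerate cases

test_that("a call set identical to the truth scores 1.0 in every populated cell", {
  sm <- get_smoke()
  cmp <- match_variants(sm$truth, sm$truth)
  expect_equal(nrow(cmp$fn), 0L)
  expect_equal(nrow(cmp$fp), 0L)
  cells <- stratify(cmp)
  populated <- cells[cells$tp + cells$fn > 0, ]
  expect_true(all(populated$tpr == 1))
  expect_true(all(populated$ppv == 1))
  expect_true(all(populated$f1 == 1))
})

test_that("empty call sets give tpr 0, undefined ppv, and f1 0", {
  sm <- get_smoke()
  cmp <- match_variants(sm$truth, variant_tbl())
  g <- glance(cmp)
  expect_equal(g$tpr, 0)
  expect_true(is.na(g$ppv))
  cells <- stratify(cmp)
  tot <- cells[cells$type == "ALL" & cells$bin == "ALL", ]
  expect_equal(tot$tpr, 0)
  expect_true(is.na(tot$ppv))
  expect_equal(tot$f1, 0)  # zero sensitivity dominates the undefined ppv
  # and the mirror case: calls with no truth
  cmp2 <- match_variants(variant_tbl(), sm$truth)
  g2 <- glance(cmp2)
  expect_true(is.na(g2$tpr))
  expect_equal(g2$ppv, 0)
})

test_that("f1 follows the harmonic-mean conventions", {
  expect_equal(f1_score(1, 1), 1)
  expect_equal(f1_score(0.5, 0.5), 0.5)
  expect_equal(f1_score(1, 0), 0)
  expect_equal(f1_score(0, 0), 0)
  expect_true(is.na(f1_score(NA, 1)))
  expect_equal(f1_score(0, NA), 0)
  expect_equal(f1_score(c(1, 0.5), c(1, 1)), c(1, 2 / 3))
})

test_that("the documented SV matching example is a TP under default parameters", {
  truth <- toy_variant("c1", 1000, "A", "<DEL>", "DEL", -500, id = "t1")
  call <- toy_variant("c1", 1050, "A", "<DEL>", "DEL", -480, id = "c1")
  cmp <- match_variants(truth, call)
  expect_equal(nrow(cmp$tp), 1L)   # distance 50 <= 100, ratio 0.96 >= 0.8
  # push either criterion out of tolerance and the match dissolves
  far <- call; far$pos <- 1101L
  expect_equal(nrow(match_variants(truth, far)$tp), 0L)
  small <- call; small$svlen <- -300L
  expect_equal(nrow(match_variants(truth, small)$tp), 0L)
})

test_that("small variants require exact normalized identity, genotype only on request", {
  truth <- toy_variant("c1", 100, "A", "C", "SNV", 0, gt1 = 1, gt2 = 0, id = "t")
  near <- toy_variant("c1", 101, "A", "C", "SNV", 0, gt1 = 1, gt2 = 0, id = "c")
  expect_equal(nrow(match_variants(truth, near)$tp), 0L)
  hom <- truth; hom$id <- "c"; hom$gt2 <- 1L
  expect_equal(nrow(match_variants(truth, hom)$tp), 1L)
  p_gt <- match_params(require_genotype = TRUE)
  expect_equal(nrow(match_variants(truth, hom, p_gt)$tp), 0L)
  phase_swap <- truth; phase_swap$id <- "c"; phase_swap$gt1 <- 0L; phase_swap$gt2 <- 1L
  expect_equal(nrow(match_variants(truth, phase_swap, p_gt)$tp), 1L)
})

test_that("repeat-shifted encodings of truth indels change nothing after normalization", {
  sm <- get_smoke()
  ref <- sm$ref
  truth <- sm$truth
  indels <- truth[truth$var_type %in% c("INS", "DEL") & abs(truth$svlen) <= 6, ]
  reencoded <- truth
  n_shifted <- 0L
  for (i in seq_len(nrow(indels))) {
    enc <- enumerate_equivalent_encodings(ref[[indels$chrom[i]]], indels[i, ])
    alt_enc <- enc[enc$pos != indels$pos[i], ]
    if (nrow(alt_enc) == 0L) next
    j <- which(reencoded$id == indels$id[i])
    reencoded[j, ] <- alt_enc[nrow(alt_enc), ]
    n_shifted <- n_shifted + 1L
  }
  expect_gt(n_shifted, 0L)
  calls <- normalize_variants(reencoded, ref)
  cmp <- match_variants(truth, dplyr::arrange(calls, chrom, pos, id))
  expect_equal(nrow(cmp$fn), 0L)
  expect_equal(nrow(cmp$fp), 0L)
})

test_that("matching is one-to-one: duplicate calls do not double-count", {
  truth <- toy_variant("c1", 1000, "A", "<DEL>", "DEL", -500, id = "t1")
  calls <- dplyr::bind_rows(
    toy_variant("c1", 1010, "A", "<DEL>", "DEL", -500, id = "c1"),
    toy_variant("c1", 1020, "A", "<DEL>", "DEL", -500, id = "c2")
  )
  cmp <- match_variants(truth, calls)
  expect_equal(nrow(cmp$tp), 1L)
  expect_equal(cmp$tp$call_id, "c1")  # closer breakpoint wins
  expect_equal(nrow(cmp$fp), 1L)
})

test_that("greedy matching agrees with the exhaustive optimum when it is unique", {
  params <- match_params()
  n_checked <- 0L
  for (s in 1:40) {
    set.seed(s)
    nt <- sample(3:10, 1)
    truth <- tibble::tibble(
      chrom = "c1",
      pos = sort(sample.int(100000L, nt)) , id = sprintf("t%02d", 1:nt),
      ref = "A", alt = "<DEL>", var_type = "DEL",
      svlen = -sample(60:2000, nt, replace = TRUE),
      ins_seq = NA_character_, dup_copies = NA_integer_, gt1 = 1L, gt2 = 1L
    )
    keep <- runif(nt) < 0.8
    calls <- truth[keep, , drop = FALSE]
    if (nrow(calls) > 0L) {
      calls$pos <- calls$pos + sample(-120:120, nrow(calls), replace = TRUE)
      calls$svlen <- -pmax(50L, as.integer(round(abs(calls$svlen) *
                                                   runif(nrow(calls), 0.7, 1.3))))
      calls$id <- sprintf("c%02d", seq_len(nrow(calls)))
    }
    pairs <- sv_candidate_pairs(truth, calls, params)
    optima <- all_max_matchings(pairs)
    if (length(optima) != 1L) next
    n_checked <- n_checked + 1L
    cmp <- match_variants(truth, calls, params)
    greedy <- if (nrow(cmp$tp) == 0L) character() else {
      sort(paste0(match(cmp$tp$id, truth$id), ":",
                  match(cmp$tp$call_id, calls$id)))
    }
    expect_identical(greedy, optima[[1]])
    expect_lte(nrow(cmp$tp), min(nrow(truth), nrow(calls)))
  }
  expect_gt(n_checked, 10L)
})

test_that("stratified cells agree with a brute-force recount and marginals add up", {
  sm <- get_smoke()
  truth <- sm$truth
  set.seed(99)
  drop <- sample.int(nrow(truth), 10)
  calls <- truth[-drop, , drop = FALSE]
  extra <- dplyr::bind_rows(
    toy_variant("ctg1", 99000, "A", "<DEL>", "DEL", -777, id = "fp1"),
    toy_variant("ctg1", 99500, "A", "C", "SNV", 0, id = "fp2")
  )
  calls <- dplyr::arrange(dplyr::bind_rows(calls, extra), chrom, pos, id)
  cmp <- match_variants(truth, calls)
  bins <- default_size_bins()
  cells <- stratify(cmp, bins)
  # independent tally straight from the tp/fn/fp sets
  recount <- function(v) table(paste(v$var_type, assign_bin(v, bins)))
  for (what in c("tp", "fn", "fp")) {
    tab <- recount(cmp[[what]])
    for (key in names(tab)) {
      parts <- strsplit(key, " ")[[1]]
      row <- cells[cells$type == parts[1] & cells$bin == parts[2], ]
      expect_equal(row[[what]], as.integer(tab[[key]]))
    }
  }
  # marginals equal the sum of their cells
  plain <- cells[cells$type != "ALL" & cells$bin != "ALL", ]
  tot <- cells[cells$type == "ALL" & cells$bin == "ALL", ]
  expect_equal(sum(plain$tp), tot$tp)
  expect_equal(sum(plain$fn), tot$fn)
  expect_equal(sum(plain$fp), tot$fp)
  expect_equal(tot$tp + tot$fn, nrow(truth))
})

test_that("comparison reports serialize to versioned JSON with null degenerate rates", {
  truth <- toy_variant("c1", 1000, "A", "<DEL>", "DEL", -500, id = "t1")
  cmp <- match_variants(truth, variant_tbl())
  p <- tempfile(fileext = ".json")
  write_variant_report_json(cmp, p)
  j <- jsonlite::read_json(p)
  expect_equal(j$schema, "simval_variant_report")
  expect_null(j$totals$ppv)
  expect_equal(j$totals$tpr, 0)
  expect_equal(j$totals$f1, 0)
})
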