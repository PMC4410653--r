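# diploid construction, map well-formedness, and liftover

ref9 <- "AAACCCGGG"

test_that("a deletion removes its span and leaves a zero-width DEL_GAP block", {
  v <- toy_variant("r", 3, "ACCC", "A", "DEL", -3, id = "d1")
  hb <- build_haplotype(ref9, v, "r", "h")
  expect_identical(hb$seq, "AAAGGG")
  expect_identical(hb$seq, apply_variants_naive(ref9, v))
  b <- hb$blocks
  expect_equal(b$feature, c("SEQ", "DEL_GAP", "SEQ"))
  expect_equal(b$host_start, c(0L, 3L, 3L))
  expect_equal(b$ref_start, c(0L, 3L, 6L))
  expect_equal(b$ref_len, c(3L, 3L, 3L))
})

test_that("an inversion substitutes the reverse complement on a minus-strand block", {
  v <- toy_variant("r", 3, "A", "<INV>", "INV", 3, id = "i1")
  hb <- build_haplotype(ref9, v, "r", "h")
  expect_identical(hb$seq, "AAAGGGGGG")
  expect_identical(hb$seq, apply_variants_naive(ref9, v))
  expect_equal(hb$blocks$strand, c("+", "-", "+"))
  expect_equal(hb$blocks$feature[2], "INV")
})

test_that("a tandem duplication keeps the original span and adds DUP_COPY blocks", {
  v <- toy_variant("r", 3, "A", "<DUP:TANDEM>", "DUP", 3, dup_copies = 2, id = "u1")
  hb <- build_haplotype(ref9, v, "r", "h")
  expect_identical(hb$seq, "AAACCCCCCGGG")
  expect_identical(hb$seq, apply_variants_naive(ref9, v))
  expect_equal(nchar(hb$seq), 12L)
  b <- hb$blocks
  expect_equal(sum(b$feature == "DUP_COPY"), 1L)
  dup <- b[b$feature == "DUP_COPY", ]
  expect_equal(c(dup$ref_start, dup$ref_len), c(3L, 3L))
  # triplication adds two copies
  v3 <- v; v3$dup_copies <- 3L
  expect_identical(build_haplotype(ref9, v3, "r", "h")$seq, "AAACCCCCCCCCGGG")
})

test_that("insertions splice novel sequence into an INS_NOVEL block", {
  v <- toy_variant("r", 3, "A", "ATT", "INS", 2, ins_seq = "TT", id = "n1")
  hb <- build_haplotype(ref9, v, "r", "h")
  expect_identical(hb$seq, "AAATTCCCGGG")
  expect_identical(hb$seq, apply_variants_naive(ref9, v))
  ins <- hb$blocks[hb$blocks$feature == "INS_NOVEL", ]
  expect_equal(c(ins$host_start, ins$host_len, ins$ref_start, ins$ref_len),
               c(3L, 2L, 3L, 0L))
})

test_that("overlapping variants and out-of-range variants are hard errors", {
  v <- dplyr::bind_rows(
    toy_variant("r", 3, "ACCC", "A", "DEL", -3, id = "d1"),
    toy_variant("r", 5, "C", "T", "SNV", 0, id = "s1")
  )
  expect_error(build_haplotype(ref9, v, "r"), "d1.*s1")
  far <- toy_variant("r", 8, "G", "<DEL>", "DEL", -5, id = "d9")
  expect_error(build_haplotype(ref9, far, "r"), "beyond")
})

test_that("lift_point matches hand-derived positions for DEL, INV and identity", {
  del <- build_haplotype(ref9, toy_variant("r", 3, "ACCC", "A", "DEL", -3, id = "d"), "r", "h")
  # host AAAGGG: host pos 4 is the second G, i.e. reference pos 7 (0-based)
  expect_equal(lift_point(del$blocks, "h", 4L)$ref_pos, 7L)
  inv <- build_haplotype(ref9, toy_variant("r", 3, "A", "<INV>", "INV", 3, id = "i"), "r", "h")
  lp <- lift_point(inv$blocks, "h", 3L)  # first base of the inverted block
  expect_equal(lp$ref_pos, 5L)
  expect_equal(lp$strand, "-")
  ident <- build_haplotype(ref9, variant_tbl(), "r", "h")
  expect_equal(lift_point(ident$blocks, "h", 7L)$ref_pos, 7L)
  expect_error(lift_point(ident$blocks, "h", 9L), "outside")
  # a duplicated base lifts to its single source position
  dup <- build_haplotype(ref9, toy_variant("r", 3, "A", "<DUP:TANDEM>", "DUP", 3,
                                           dup_copies = 2, id = "u"), "r", "h")
  expect_equal(lift_point(dup$blocks, "h", 6L)$ref_pos, 3L)
})

test_that("lift_interval splits at block edges and supports reconstruction", {
  del <- build_haplotype(ref9, toy_variant("r", 3, "ACCC", "A", "DEL", -3, id = "d"), "r", "h")
  segs <- lift_interval(del$blocks, "h", 1L, 5L)  # spans the deletion join
  live <- segs[segs$len > 0, ]
  expect_equal(nrow(live), 2L)
  expect_true("DEL_GAP" %in% segs$feature)
  got <- paste0(substr(ref9, live$ref_start[1] + 1, live$ref_start[1] + live$len[1]),
                substr(ref9, live$ref_start[2] + 1, live$ref_start[2] + live$len[2]))
  expect_identical(got, substr(del$seq, 2, 5))
  inv <- build_haplotype(ref9, toy_variant("r", 3, "A", "<INV>", "INV", 3, id = "i"), "r", "h")
  segs2 <- lift_interval(inv$blocks, "h", 2L, 5L)  # crosses the inversion edge
  expect_equal(segs2$strand, c("+", "-"))
})

test_that("whole-genome reconstruction and length conservation hold on the smoke fixture", {
  sm <- get_smoke()
  dip <- sm$dip
  validate_genome_map(dip$map, nchar(dip$haplotypes))
  for (hap in c("A", "B")) {
    tv <- if (hap == "A") dip$truth_hapA else dip$truth_hapB
    expected <- nchar(sm$ref[["ctg1"]]) +
      sum(tv$svlen[tv$var_type == "INS"]) +
      sum(tv$svlen[tv$var_type == "DEL"]) +
      sum((tv$dup_copies[tv$var_type == "DUP"] - 1L) * tv$svlen[tv$var_type == "DUP"])
    ctg <- paste0("ctg1_hap", hap)
    expect_equal(nchar(dip$haplotypes[[ctg]]), expected)
    expect_identical(reconstruct_host(dip, sm$truth, sm$ref, ctg),
                     dip$haplotypes[[ctg]])
  }
})

test_that("an empty truth set reproduces the reference; homozygous truth gives identical haplotypes", {
  ref <- c(c1 = strrep("ACGTT", 40))
  dip0 <- build_diploid(ref, variant_tbl())
  expect_identical(unname(dip0$haplotypes[["c1_hapA"]]), ref[["c1"]])
  expect_identical(unname(dip0$haplotypes[["c1_hapB"]]), ref[["c1"]])
  expect_equal(nrow(dip0$map), 2L)
  expect_equal(unique(dip0$map$feature), "SEQ")
  hom <- dplyr::bind_rows(
    toy_variant("c1", 10, "C", "A", "SNV", 0, id = "a"),
    toy_variant("c1", 50, "G", "<DEL>", "DEL", -20, id = "b"),
    toy_variant("c1", 100, "G", "<INV>", "INV", 15, id = "c")
  )
  dip <- build_diploid(ref, hom)
  expect_identical(unname(dip$haplotypes[["c1_hapA"]]),
                   unname(dip$haplotypes[["c1_hapB"]]))
  # one het SNV on hapA leaves hapB untouched
  het <- toy_variant("c1", 10, "C", "A", "SNV", 0, gt1 = 1, gt2 = 0, id = "h")
  dip2 <- build_diploid(ref, het)
  expect_identical(unname(dip2$haplotypes[["c1_hapB"]]), ref[["c1"]])
  expect_false(identical(unname(dip2$haplotypes[["c1_hapA"]]), ref[["c1"]]))
})

test_that("the genome map round-trips through its TSV format", {
  sm <- get_smoke()
  p <- tempfile(fileext = ".tsv")
  write_genome_map(sm$dip$map, p)
  back <- read_genome_map(p)
  expect_identical(as.data.frame(back), as.data.frame(sm$dip$map))
  expect_error(read_genome_map(tempfile_with <- {
    f <- tempfile(); writeLines("host_contig\thost_start", f); f
  }), "format header")
})

test_that("the map validator rejects malformed block sets", {
  sm <- get_smoke()
  bad <- sm$dip$map
  bad$host_start[2] <- bad$host_start[2] + 1L
  expect_error(validate_genome_map(bad), "tile")
  bad2 <- sm$dip$map
  bad2$strand[bad2$feature == "INV"][1] <- "+"
  expect_error(validate_genome_map(bad2), "INV")
})
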