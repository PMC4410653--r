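# Synthetic reference / variant-database fixtures. These stand in for real
# resources (reference assembly, variant databases, known insertion
# sequences) so that the whole pipeline can run without any downloads. All
# outputs are deterministic given the spec seed.

#' Describe a synthetic reference fixture
#'
#' @param n_contigs Number of contigs.
#' @param contig_len Length of each contig in bp (>= 1000).
#' @param gc Target GC fraction, strictly between 0 and 1.
#' @param n_repeat_tracts Short tandem repeat tracts embedded per contig
#'   (these exercise indel normalization).
#' @param repeat_units Candidate repeat unit strings.
#' @param tract_copies Inclusive range of copy counts per tract.
#' @param seed RNG seed; every fixture is reproducible byte-for-byte from
#'   `(spec, seed)`.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_contigs = 1L, contig_len = 100000L, gc = 0.5,
                         n_repeat_tracts = 20L,
                         repeat_units = c("A", "CA", "CAG"),
                         tract_copies = c(8L, 20L), seed = 1L) {
  stopifnot(contig_len >= 1000L, gc > 0, gc < 1, n_contigs >= 1L)
  structure(
    list(n_contigs = n_contigs, contig_len = as.integer(contig_len), gc = gc,
         n_repeat_tracts = as.integer(n_repeat_tracts),
         repeat_units = repeat_units,
         tract_copies = as.integer(tract_copies), seed = as.integer(seed)),
    class = "fixture_spec"
  )
}

#' Generate a synthetic reference genome
#'
#' Bases are drawn i.i.d. at the target GC content; short tandem repeat
#' tracts (e.g. `CA` x 15) are then embedded at recorded, non-overlapping
#' positions so downstream indel placement can deliberately hit repeat
#' context.
#'
#' @param spec A [fixture_spec()].
#' @return A list with `sequences` (named character vector of contigs) and
#'   `tracts` (tibble: `chrom`, `start`, `end` 1-based inclusive, `unit`,
#'   `copies`).
#' @export
make_reference <- function(spec) {
  local_seed(spec$seed, {
    seqs <- character(spec$n_contigs)
    names(seqs) <- paste0("ctg", seq_len(spec$n_contigs))
    tract_rows <- list()
    for (ci in seq_len(spec$n_contigs)) {
      s <- random_dna(spec$contig_len, spec$gc)
      taken_start <- integer(); taken_end <- integer()
      for (ti in seq_len(spec$n_repeat_tracts)) {
        unit <- sample(spec$repeat_units, 1L)
        copies <- sample(seq(spec$tract_copies[1], spec$tract_copies[2]), 1L)
        tract <- strrep(unit, copies)
        w <- nchar(tract)
        for (attempt in 1:50) {
          start <- sample.int(spec$contig_len - w - 200L, 1L) + 100L
          end <- start + w - 1L
          if (!any(start <= taken_end + 50L & end >= taken_start - 50L)) break
          start <- NA_integer_
        }
        if (is.na(start)) next
        substr(s, start, end) <- tract
        taken_start <- c(taken_start, start); taken_end <- c(taken_end, end)
        tract_rows[[length(tract_rows) + 1L]] <- tibble::tibble(
          chrom = names(seqs)[ci], start = start, end = end,
          unit = unit, copies = copies
        )
      }
      seqs[ci] <- s
    }
    list(sequences = seqs, tracts = dplyr::bind_rows(tract_rows))
  })
}

#' Generate an insertion-sequence pool
#'
#' A small stand-in for a database of known insertion donor sequences:
#' random DNA strings spanning the requested length range.
#'
#' @param n Number of donor sequences.
#' @param len_range Inclusive donor length range in bp.
#' @param seed RNG seed.
#' @return Named character vector of donor sequences.
#' @export
make_insertion_pool <- function(n = 10L, len_range = c(200L, 3000L), seed = 1L) {
  local_seed(derive_seed(seed, 31L), {
    lens <- sample(seq(len_range[1], len_range[2]), n, replace = TRUE)
    stats::setNames(vapply(lens, random_dna, character(1)),
                    paste0("donor", seq_len(n)))
  })
}

# pick a position whose footprint [pos0, pos0+width) keeps >= min_gap bp from
# every accepted footprint; simple rejection sampling
place_nonoverlapping <- function(contig_len, width, taken_start, taken_end,
                                 min_gap, lo = 2L, hi = NULL, n_try = 200L) {
  hi <- hi %||% (contig_len - width - 1L)
  if (hi < lo) return(NA_integer_)
  for (i in seq_len(n_try)) {
    p <- sample(seq(lo, hi), 1L)
    if (!any(p <= taken_end + min_gap & (p + width - 1L) >= taken_start - min_gap)) {
      return(p)
    }
  }
  NA_integer_
}

#' Generate a synthetic variant database VCF
#'
#' Emulates a public variant database: requested counts of SNVs, small
#' indels and SVs (DEL/INS/DUP/INV) with sizes uniform in the requested
#' ranges, placed uniformly subject to a minimum pairwise gap so the whole
#' database can be applied to one haplotype without overlap. A configurable
#' fraction of small indels is placed inside the reference's repeat tracts
#' and emitted in a deliberately right-shifted (non-canonical) encoding to
#' stress normalization. All genotypes are `1|1` placeholders; real
#' genotypes are assigned at sampling time.
#'
#' @param reference Output of [make_reference()] (list with `sequences` and
#'   `tracts`).
#' @param n_snv,n_indel,n_sv Requested record counts; SVs are split evenly
#'   across DEL/INS/DUP/INV.
#' @param indel_size,sv_size Inclusive size ranges in bp.
#' @param repeat_fraction Fraction of indels targeted at repeat tracts.
#' @param min_gap Minimum bp between any two records' reference footprints.
#' @param seed RNG seed.
#' @return Variant tibble (not yet normalized: repeat-context indels are
#'   intentionally right-shifted).
#' @export
make_variant_db <- function(reference, n_snv = 200L, n_indel = 80L, n_sv = 20L,
                            indel_size = c(1L, 20L), sv_size = c(50L, 2000L),
                            repeat_fraction = 0.25, min_gap = 10L, seed = 1L) {
  seqs <- reference$sequences
  tracts <- reference$tracts
  local_seed(derive_seed(seed, 7L), {
    rows <- list()
    taken <- lapply(seqs, function(x) list(s = integer(), e = integer()))
    add_taken <- function(chrom, s, e) {
      taken[[chrom]]$s <<- c(taken[[chrom]]$s, s)
      taken[[chrom]]$e <<- c(taken[[chrom]]$e, e)
    }
    pick_contig <- function() sample(names(seqs), 1L, prob = nchar(seqs))
    emit <- function(row) rows[[length(rows) + 1L]] <<- row
    n_fail <- 0L

    # SNVs
    for (i in seq_len(n_snv)) {
      chrom <- pick_contig()
      p <- place_nonoverlapping(nchar(seqs[[chrom]]), 1L,
                                taken[[chrom]]$s, taken[[chrom]]$e, min_gap)
      if (is.na(p)) { n_fail <- n_fail + 1L; next }
      rb <- substr(seqs[[chrom]], p, p)
      ab <- sample(setdiff(c("A", "C", "G", "T"), rb), 1L)
      add_taken(chrom, p, p)
      emit(tibble::tibble(chrom = chrom, pos = p, id = sprintf("db_snv_%04d", i),
                          ref = rb, alt = ab, var_type = "SNV", svlen = 0L,
                          ins_seq = NA_character_, dup_copies = NA_integer_,
                          gt1 = 1L, gt2 = 1L))
    }

    # small indels; a fraction inside repeat tracts, right-shifted
    n_rep <- round(n_indel * repeat_fraction)
    usable_tracts <- if (nrow(tracts) > 0) tracts[nchar(tracts$unit) * 1L <= indel_size[2], ] else tracts
    for (i in seq_len(n_indel)) {
      in_repeat <- i <= n_rep && nrow(usable_tracts) > 0
      is_del <- (i %% 2L) == 0L
      if (in_repeat) {
        tr <- usable_tracts[sample.int(nrow(usable_tracts), 1L), ]
        chrom <- tr$chrom
        unit_w <- nchar(tr$unit)
        # right-shifted encoding anchored just before the tract's last unit
        if (is_del) {
          anchor <- tr$end - unit_w
          rb <- substr(seqs[[chrom]], anchor, anchor)
          ref <- paste0(rb, substr(seqs[[chrom]], anchor + 1L, anchor + unit_w))
          alt <- rb
          svlen <- -unit_w
          fs <- tr$start - 1L; fe <- tr$end  # footprint: whole tract
        } else {
          anchor <- tr$end
          rb <- substr(seqs[[chrom]], anchor, anchor)
          ref <- rb
          alt <- paste0(rb, tr$unit)
          svlen <- unit_w
          fs <- tr$start - 1L; fe <- tr$end
        }
        if (any(fs <= taken[[chrom]]$e + min_gap & fe >= taken[[chrom]]$s - min_gap)) next
        add_taken(chrom, fs, fe)
        emit(tibble::tibble(chrom = chrom, pos = anchor,
                            id = sprintf("db_indel_%04d", i), ref = ref, alt = alt,
                            var_type = ifelse(is_del, "DEL", "INS"),
                            svlen = as.integer(svlen),
                            ins_seq = ifelse(is_del, NA_character_, tr$unit),
                            dup_copies = NA_integer_, gt1 = 1L, gt2 = 1L))
      } else {
        chrom <- pick_contig()
        w <- sample(seq(max(1L, indel_size[1]), indel_size[2]), 1L)
        p <- place_nonoverlapping(nchar(seqs[[chrom]]), w + 1L,
                                  taken[[chrom]]$s, taken[[chrom]]$e, min_gap)
        if (is.na(p)) { n_fail <- n_fail + 1L; next }
        rb <- substr(seqs[[chrom]], p, p)
        if (is_del) {
          ref <- substr(seqs[[chrom]], p, p + w)
          alt <- rb
          svlen <- -w
          ins <- NA_character_
        } else {
          ref <- rb
          ins <- random_dna(w)
          alt <- paste0(rb, ins)
          svlen <- w
        }
        add_taken(chrom, p, p + w)
        emit(tibble::tibble(chrom = chrom, pos = p,
                            id = sprintf("db_indel_%04d", i), ref = ref, alt = alt,
                            var_type = ifelse(is_del, "DEL", "INS"),
                            svlen = as.integer(svlen), ins_seq = ins,
                            dup_copies = NA_integer_, gt1 = 1L, gt2 = 1L))
      }
    }

    # SVs: DEL / INS / DUP / INV round-robin, symbolic encoding
    sv_types <- rep_len(c("DEL", "INS", "DUP", "INV"), n_sv)
    sv_hi <- min(sv_size[2], floor(min(nchar(seqs)) / 10))
    for (i in seq_len(n_sv)) {
      ty <- sv_types[i]
      chrom <- pick_contig()
      if (sv_hi < sv_size[1]) { n_fail <- n_fail + 1L; next }
      w <- sample(seq(sv_size[1], sv_hi), 1L)
      span <- if (ty == "INS") 1L else w + 1L
      dupc <- if (ty == "DUP") sample(2:3, 1L) else NA_integer_
      p <- place_nonoverlapping(nchar(seqs[[chrom]]), span,
                                taken[[chrom]]$s, taken[[chrom]]$e, min_gap)
      if (is.na(p)) { n_fail <- n_fail + 1L; next }
      add_taken(chrom, p, p + span - 1L)
      emit(tibble::tibble(
        chrom = chrom, pos = p, id = sprintf("db_sv_%s_%04d", tolower(ty), i),
        ref = substr(seqs[[chrom]], p, p),
        alt = switch(ty, DEL = "<DEL>", INS = "<INS>", INV = "<INV>", DUP = "<DUP:TANDEM>"),
        var_type = ty, svlen = as.integer(ifelse(ty == "DEL", -w, w)),
        ins_seq = NA_character_, dup_copies = dupc, gt1 = 1L, gt2 = 1L
      ))
    }
    if (n_fail > 0L) {
      if (length(rows) == 0L) {
        stop("genome too small for requested database counts", call. = FALSE)
      }
      warning(n_fail, " database records could not be placed (genome too dense); ",
              "feasible maximum reached", call. = FALSE)
    }
    out <- as_variant_tbl(dplyr::bind_rows(rows))
    dplyr::arrange(out, .data$chrom, .data$pos, .data$id)
  })
}

#' Build the default smoke fixture
#'
#' One 100 kb contig with repeat tracts, a variant database large enough to
#' sample 50 SNVs / 20 indels / 5 SVs from, and an insertion pool. This is
#' the self-contained input set used by the end-to-end examples and tests.
#'
#' @param seed RNG seed.
#' @param contig_len Contig length in bp.
#' @return List with `reference` (from [make_reference()]), `db` (variant
#'   tibble), `pool` (character vector), and `spec` (the fixture spec).
#' @export
smoke_fixture <- function(seed = 1L, contig_len = 100000L) {
  spec <- fixture_spec(n_contigs = 1L, contig_len = contig_len, seed = seed)
  reference <- make_reference(spec)
  db <- make_variant_db(reference, n_snv = 200L, n_indel = 80L, n_sv = 20L,
                        seed = seed)
  pool <- make_insertion_pool(seed = seed)
  list(reference = reference, db = db, pool = pool, spec = spec)
}
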