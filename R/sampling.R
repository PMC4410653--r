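# Truth-set construction: sample variants from a database, assign phased
# genotypes, and resolve concrete insertion sequences from a donor pool.

#' Describe a variant sampling request
#'
#' @param n_snv,n_indel,n_sv Requested counts per category. An indel is an
#'   insertion or deletion smaller than 50 bp; everything else non-SNV
#'   (including all INV/DUP) counts as an SV.
#' @param het_fraction Probability that a sampled variant is heterozygous;
#'   heterozygous variants land on haplotype A or B with probability 1/2
#'   each. Default 0.6, roughly the het/hom balance of a human genome.
#' @param min_gap Minimum reference-space separation (bp) between the
#'   footprints of any two accepted variants.
#' @param indel_size,sv_size Inclusive `|svlen|` eligibility filters.
#' @param seed RNG seed; sampling is fully deterministic given
#'   `(db, spec, seed)`.
#' @return A `sampling_spec` list.
#' @export
sampling_spec <- function(n_snv = 0L, n_indel = 0L, n_sv = 0L,
                          het_fraction = 0.6, min_gap = 10L,
                          indel_size = c(1L, 49L), sv_size = c(50L, Inf),
                          seed = 1L) {
  stopifnot(n_snv >= 0L, n_indel >= 0L, n_sv >= 0L,
            het_fraction >= 0, het_fraction <= 1, min_gap >= 1L)
  structure(
    list(n_snv = as.integer(n_snv), n_indel = as.integer(n_indel),
         n_sv = as.integer(n_sv), het_fraction = het_fraction,
         min_gap = as.integer(min_gap), indel_size = indel_size,
         sv_size = sv_size, seed = as.integer(seed)),
    class = "sampling_spec"
  )
}

variant_category <- function(v) {
  size <- abs(v$svlen)
  dplyr::case_when(
    v$var_type == "SNV" | v$var_type == "MNP" ~ "snv",
    v$var_type %in% c("INS", "DEL") & size < 50L ~ "indel",
    TRUE ~ "sv"
  )
}

#' Sample a phased truth set from a variant database
#'
#' Shuffles the database with the spec seed, then accepts records in
#' shuffled order (rejection sampling) until each category quota is met,
#' skipping any record whose reference footprint comes within `min_gap` bp
#' of an already accepted one. Genotypes are then drawn: heterozygous with
#' probability `het_fraction` (haplotype A or B with probability 1/2 each),
#' homozygous `1|1` otherwise.
#'
#' @param db Normalized variant tibble (e.g. from [make_variant_db()] after
#'   [normalize_variants()], or [read_vcf()]).
#' @param spec A [sampling_spec()].
#' @param reference Named character vector or DNAStringSet (used for
#'   validity checks).
#' @return Phased variant tibble sorted by `(chrom, pos)`. If a category
#'   has too few eligible records, all eligible ones are returned with a
#'   warning about the shortfall.
#' @export
sample_variants <- function(db, spec, reference) {
  reference <- ref_as_character(reference)
  quota <- c(snv = spec$n_snv, indel = spec$n_indel, sv = spec$n_sv)
  if (nrow(db) == 0L) {
    if (sum(quota) > 0L) warning("empty database; sampled 0 of ", sum(quota), call. = FALSE)
    return(variant_tbl())
  }
  cat_all <- variant_category(db)
  size <- abs(db$svlen)
  eligible <- (cat_all == "snv") |
    (cat_all == "indel" & size >= spec$indel_size[1] & size <= spec$indel_size[2]) |
    (cat_all == "sv" & size >= spec$sv_size[1] & size <= spec$sv_size[2])

  local_seed(spec$seed, {
    ord <- sample.int(nrow(db))
    taken <- lapply(stats::setNames(nm = unique(db$chrom)),
                    function(x) list(s = integer(), e = integer()))
    got <- c(snv = 0L, indel = 0L, sv = 0L)
    keep <- integer()
    fp <- variant_footprint(db)
    for (i in ord) {
      if (!eligible[i]) next
      ct <- cat_all[i]
      if (got[[ct]] >= quota[[ct]]) next
      tk <- taken[[db$chrom[i]]]
      s <- fp$start0[i]; e <- fp$end0[i] - 1L
      if (any(s <= tk$e + spec$min_gap & e >= tk$s - spec$min_gap)) next
      taken[[db$chrom[i]]]$s <- c(tk$s, s)
      taken[[db$chrom[i]]]$e <- c(tk$e, e)
      got[[ct]] <- got[[ct]] + 1L
      keep <- c(keep, i)
      if (all(got >= quota)) break
    }
    short <- quota - got
    if (any(short > 0L)) {
      warning("sampling shortfall: ",
              paste(sprintf("%s %d/%d", names(quota), got, quota)[short > 0],
                    collapse = ", "), call. = FALSE)
    }
    out <- db[keep, , drop = FALSE]
    # phased genotype assignment, in accepted order
    n <- nrow(out)
    het <- stats::runif(n) < spec$het_fraction
    hapA <- stats::runif(n) < 0.5
    out$gt1 <- ifelse(het, ifelse(hapA, 1L, 0L), 1L)
    out$gt2 <- ifelse(het, ifelse(hapA, 0L, 1L), 1L)
    dplyr::arrange(out, .data$chrom, .data$pos, .data$id)
  })
}

#' Draw a novel insertion sequence
#'
#' If the donor pool holds any sequence at least as long as requested, a
#' uniformly chosen window of the requested length is cut from a uniformly
#' chosen eligible donor; otherwise the sequence is i.i.d. uniform ACGT.
#' Uses the current RNG state (seed at the caller).
#'
#' @param length Requested length in bp (>= 1).
#' @param pool Character vector of donor sequences (may be empty).
#' @return DNA string of exactly `length` bp.
#' @export
make_insertion_sequence <- function(length, pool = character()) {
  if (length < 1L) stop("insertion length must be >= 1", call. = FALSE)
  eligible <- pool[nchar(pool) >= length]
  if (length(eligible) > 0L) {
    donor <- eligible[[sample.int(length(eligible), 1L)]]
    start <- sample.int(nchar(donor) - length + 1L, 1L)
    substr(donor, start, start + length - 1L)
  } else {
    paste(sample(c("A", "C", "G", "T"), length, replace = TRUE), collapse = "")
  }
}

#' Resolve symbolic insertions to concrete sequences
#'
#' Fills `ins_seq` for every INS that lacks one, drawing from the donor
#' pool via [make_insertion_sequence()]. The result is the final truth set
#' content, ready for [write_vcf()] and [build_diploid()].
#'
#' @param sampled Variant tibble (normalized, phased).
#' @param pool Character vector of donor sequences.
#' @param seed RNG seed for the draws.
#' @return Variant tibble with all INS records carrying `ins_seq` of length
#'   `svlen`.
#' @export
resolve_truth <- function(sampled, pool = character(), seed = 1L) {
  v <- sampled
  todo <- which(v$var_type == "INS" & is.na(v$ins_seq))
  if (length(todo) > 0L) {
    local_seed(derive_seed(seed, 17L), {
      for (i in todo) {
        v$ins_seq[i] <- make_insertion_sequence(v$svlen[i], pool)
      }
    })
  }
  v
}

#' Sample and resolve a truth set in one call
#'
#' Convenience wrapper: [sample_variants()] then [resolve_truth()] (seeded
#' from the sampling spec).
#'
#' @inheritParams sample_variants
#' @param pool Insertion donor pool.
#' @return Phased, fully resolved truth variant tibble.
#' @export
sample_truth <- function(db, spec, reference, pool = character()) {
  resolve_truth(sample_variants(db, spec, reference), pool, seed = spec$seed)
}
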