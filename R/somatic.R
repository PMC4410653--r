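# Tumor/normal workflow: two-pass simulation sharing one germline truth,
# read mixing to model normal contamination, and somatic call validation.

#' Build a matched tumor/normal genome pair
#'
#' Samples one germline truth set `G` with the spec seed; the normal
#' genome carries exactly `G`, the tumor genome carries `G` plus the
#' somatic set `S` applied on top. Because both passes share the seed, the
#' germline content of the two genomes is byte-identical. Somatic variants
#' whose reference footprints collide with `G` (or with each other) are
#' dropped and reported. Somatic genotypes are drawn from a separate RNG
#' stream so the germline draws are untouched.
#'
#' @param reference Named character vector or DNAStringSet.
#' @param db Normalized germline database variant tibble.
#' @param somatic Normalized somatic variant tibble (genotypes in it are
#'   ignored and re-drawn).
#' @param spec Germline [sampling_spec()], shared by both passes.
#' @param pool Insertion donor pool.
#' @param somatic_het_fraction Probability a somatic variant is
#'   heterozygous.
#' @return List with `normal` and `tumor` (each a [build_diploid()]
#'   result), `germline_truth`, `somatic_truth` (exactly the applied `S`)
#'   and `dropped` (ids of colliding somatic records).
#' @export
build_tumor_normal <- function(reference, db, somatic, spec,
                               pool = character(), somatic_het_fraction = 0.6) {
  reference <- ref_as_character(reference)
  G <- sample_truth(db, spec, reference, pool)

  # drop somatic records colliding with germline footprints or each other
  S <- somatic
  dropped <- character()
  if (nrow(S) > 0L) {
    S <- dplyr::arrange(S, .data$chrom, .data$pos)
    gfp <- variant_footprint(G); sfp <- variant_footprint(S)
    keep <- logical(nrow(S))
    acc_s <- list(); acc_e <- list()
    for (ctg in unique(c(G$chrom, S$chrom))) {
      acc_s[[ctg]] <- gfp$start0[G$chrom == ctg]
      acc_e[[ctg]] <- gfp$end0[G$chrom == ctg]
    }
    for (i in seq_len(nrow(S))) {
      ctg <- S$chrom[i]
      clash <- any(sfp$start0[i] < acc_e[[ctg]] & sfp$end0[i] > acc_s[[ctg]])
      if (clash) {
        dropped <- c(dropped, S$id[i])
      } else {
        keep[i] <- TRUE
        acc_s[[ctg]] <- c(acc_s[[ctg]], sfp$start0[i])
        acc_e[[ctg]] <- c(acc_e[[ctg]], sfp$end0[i])
      }
    }
    if (length(dropped) > 0L) {
      message("dropped ", length(dropped), " somatic variants colliding with ",
              "existing footprints: ", paste(dropped, collapse = ", "))
    }
    S <- S[keep, , drop = FALSE]
    if (nrow(S) > 0L) {
      local_seed(derive_seed(spec$seed, 104729L), {
        het <- stats::runif(nrow(S)) < somatic_het_fraction
        hapA <- stats::runif(nrow(S)) < 0.5
        S$gt1 <- ifelse(het, ifelse(hapA, 1L, 0L), 1L)
        S$gt2 <- ifelse(het, ifelse(hapA, 0L, 1L), 1L)
      })
      S <- resolve_truth(S, pool, seed = derive_seed(spec$seed, 104730L))
    }
  }

  tumor_truth <- dplyr::arrange(dplyr::bind_rows(G, S), .data$chrom, .data$pos,
                                .data$id)
  list(
    normal = build_diploid(reference, G),
    tumor = build_diploid(reference, tumor_truth),
    germline_truth = G,
    somatic_truth = S,
    dropped = dropped
  )
}

#' Mix tumor and normal read pairs at a given tumor fraction
#'
#' Each emitted pair is drawn from the tumor pool with probability `alpha`
#' and from the normal pool otherwise, sampling without replacement within
#' each pool and keeping mates together. The read-id prefixes of the two
#' input sets keep the origin recoverable from the truth payload.
#'
#' @param normal_reads,tumor_reads Annotated reads tibbles (use distinct
#'   `prefix` values when simulating).
#' @param alpha Tumor fraction (purity) in `[0, 1]`.
#' @param n_pairs Number of pairs to emit.
#' @param seed RNG seed.
#' @return Reads tibble of `n_pairs` pairs with an `origin` column
#'   (`"tumor"`/`"normal"`) and re-numbered `pair_id` in emission order.
#' @export
mix_reads <- function(normal_reads, tumor_reads, alpha, n_pairs, seed = 1L) {
  stopifnot(alpha >= 0, alpha <= 1, n_pairs >= 1L)
  n_pool <- unique(normal_reads$pair_id)
  t_pool <- unique(tumor_reads$pair_id)
  local_seed(derive_seed(seed, 271828L), {
    from_tumor <- stats::runif(n_pairs) < alpha
    n_t <- sum(from_tumor); n_n <- n_pairs - n_t
    if (n_t > length(t_pool) || n_n > length(n_pool)) {
      # achievable maximum given the realized draw fractions
      stop("read pools exhausted: need ", n_t, " tumor and ", n_n,
           " normal pairs but have ", length(t_pool), " and ", length(n_pool),
           "; achievable maximum N is ",
           min(floor(length(t_pool) / max(alpha, 1e-9)),
               floor(length(n_pool) / max(1 - alpha, 1e-9))),
           call. = FALSE)
    }
    pick_t <- sample(t_pool, n_t)
    pick_n <- sample(n_pool, n_n)
    t_by <- split(seq_len(nrow(tumor_reads)), tumor_reads$pair_id)
    n_by <- split(seq_len(nrow(normal_reads)), normal_reads$pair_id)
    grab <- function(reads, by, picks, slots, origin) {
      rows_per <- by[as.character(picks)]
      out <- reads[unlist(rows_per, use.names = FALSE), , drop = FALSE]
      out$origin <- origin
      out$pair_id <- rep(slots, lengths(rows_per))
      out
    }
    out <- dplyr::bind_rows(
      grab(tumor_reads, t_by, pick_t, which(from_tumor), "tumor"),
      grab(normal_reads, n_by, pick_n, which(!from_tumor), "normal")
    )
    out <- dplyr::arrange(out, .data$pair_id, .data$mate)
    attr(out, "sidecar") <- dplyr::bind_rows(attr(normal_reads, "sidecar"),
                                             attr(tumor_reads, "sidecar"))
    out
  })
}

#' Validate somatic calls against somatic and germline truth
#'
#' Runs [match_variants()] against the somatic truth; FP calls that match
#' a germline truth variant are additionally flagged as germline leaks
#' (they remain FP for precision).
#'
#' @param calls Normalized call variant tibble.
#' @param somatic_truth,germline_truth Normalized truth tibbles.
#' @param params A [match_params()].
#' @return List with `comparison` (a `variant_comparison`),
#'   `germline_leaks` (count) and `leak_ids` (FP call ids flagged as
#'   leaks).
#' @export
validate_somatic <- function(calls, somatic_truth, germline_truth,
                             params = match_params()) {
  comparison <- match_variants(somatic_truth, calls, params)
  leak_ids <- character()
  if (nrow(comparison$fp) > 0L && nrow(germline_truth) > 0L) {
    leak_cmp <- match_variants(germline_truth, comparison$fp, params)
    leak_ids <- leak_cmp$tp$call_id
  }
  list(comparison = comparison, germline_leaks = length(leak_ids),
       leak_ids = leak_ids)
}
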