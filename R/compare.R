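# Variant-call validation: canonical comparison of a call set against the
# truth set with TPR/PPV/F1 stratified by variant type and size bin.

#' Variant matching parameters
#'
#' @param sv_threshold Size (bp) at and above which tolerant SV matching
#'   applies; smaller indels and all SNV/MNP must match exactly after
#'   normalization.
#' @param bp_tolerance Maximum breakpoint start distance (bp) for an SV
#'   match.
#' @param size_ratio_min Minimum `min(size) / max(size)` for an SV match.
#' @param require_genotype Also require genotype agreement (unordered
#'   allele pair) for small variants.
#' @return A `match_params` list.
#' @export
match_params <- function(sv_threshold = 50L, bp_tolerance = 100L,
                         size_ratio_min = 0.8, require_genotype = FALSE) {
  stopifnot(sv_threshold >= 1L, bp_tolerance >= 0L,
            size_ratio_min > 0, size_ratio_min <= 1)
  structure(list(sv_threshold = as.integer(sv_threshold),
                 bp_tolerance = as.integer(bp_tolerance),
                 size_ratio_min = size_ratio_min,
                 require_genotype = require_genotype),
            class = "match_params")
}

#' Harmonic mean of precision and sensitivity
#'
#' `2pr / (p + r)`. A zero on either side forces F1 to 0 (an empty call set
#' has F1 0 even though its precision is undefined); otherwise an `NA`
#' (undefined rate) propagates to `NA`.
#'
#' @param tpr,ppv Rates in `[0, 1]`, possibly `NA`.
#' @return F1 score, vectorized.
#' @export
f1_score <- function(tpr, ppv) {
  zero <- (!is.na(tpr) & tpr == 0) | (!is.na(ppv) & ppv == 0)
  out <- ifelse(zero, 0,
                ifelse(is.na(tpr) | is.na(ppv), NA_real_,
                       2 * tpr * ppv / (tpr + ppv)))
  as.numeric(out)
}

small_key <- function(v, require_genotype) {
  key <- paste(v$chrom, v$pos, v$ref, v$alt, sep = "\r")
  if (require_genotype) {
    key <- paste(key, pmin(v$gt1, v$gt2), pmax(v$gt1, v$gt2), sep = "\r")
  }
  key
}

is_small <- function(v, sv_threshold) {
  v$var_type %in% c("SNV", "MNP") | abs(v$svlen) < sv_threshold
}

#' Match a call set against the truth set
#'
#' Small variants (all SNV/MNP, and indels below `sv_threshold`) match by
#' identity of `(chrom, pos, ref, alt)` after normalization (plus genotype
#' when `require_genotype`). SVs match when the type agrees, breakpoint
#' starts are within `bp_tolerance`, and the size ratio is at least
#' `size_ratio_min` (insert content is not compared). Matching is one to
#' one, greedy in order of increasing breakpoint distance with ties broken
#' by larger size ratio and then truth position. Unmatched truth records
#' are FN; unmatched calls are FP.
#'
#' @param truth,calls Normalized variant tibbles.
#' @param params A [match_params()].
#' @return A `variant_comparison`: list with `tp` (truth rows plus matched
#'   `call_id`/`call_pos`/`call_svlen`), `fn`, `fp`, and `params`.
#' @export
match_variants <- function(truth, calls, params = match_params()) {
  t_small <- is_small(truth, params$sv_threshold)
  c_small <- is_small(calls, params$sv_threshold)

  # exact matching of small variants, one-to-one per key
  tk <- small_key(truth, params$require_genotype)
  ck <- small_key(calls, params$require_genotype)
  t_idx_small <- which(t_small); c_idx_small <- which(c_small)
  tp_t <- integer(); tp_c <- integer()
  if (length(t_idx_small) > 0L && length(c_idx_small) > 0L) {
    pool <- split(c_idx_small, ck[c_idx_small])
    for (i in t_idx_small) {
      hit <- pool[[tk[i]]]
      if (length(hit) > 0L) {
        tp_t <- c(tp_t, i); tp_c <- c(tp_c, hit[1])
        pool[[tk[i]]] <- hit[-1]
      }
    }
  }

  # tolerant greedy matching of SVs
  t_idx_sv <- which(!t_small); c_idx_sv <- which(!c_small)
  if (length(t_idx_sv) > 0L && length(c_idx_sv) > 0L) {
    cand <- tidyr::expand_grid(ti = t_idx_sv, ci = c_idx_sv)
    cand <- cand[truth$var_type[cand$ti] == calls$var_type[cand$ci] &
                   truth$chrom[cand$ti] == calls$chrom[cand$ci], , drop = FALSE]
    if (nrow(cand) > 0L) {
      dist <- abs(truth$pos[cand$ti] - calls$pos[cand$ci])
      ts <- abs(truth$svlen[cand$ti]); cs <- abs(calls$svlen[cand$ci])
      ratio <- pmin(ts, cs) / pmax(ts, cs)
      ok <- dist <= params$bp_tolerance & ratio >= params$size_ratio_min
      cand <- cand[ok, , drop = FALSE]
      dist <- dist[ok]; ratio <- ratio[ok]
      o <- order(dist, -ratio, truth$pos[cand$ti])
      used_t <- logical(nrow(truth)); used_c <- logical(nrow(calls))
      for (k in o) {
        ti <- cand$ti[k]; ci <- cand$ci[k]
        if (used_t[ti] || used_c[ci]) next
        used_t[ti] <- TRUE; used_c[ci] <- TRUE
        tp_t <- c(tp_t, ti); tp_c <- c(tp_c, ci)
      }
    }
  }

  tp <- truth[tp_t, , drop = FALSE]
  if (nrow(tp) > 0L) {
    tp$call_id <- calls$id[tp_c]
    tp$call_pos <- calls$pos[tp_c]
    tp$call_svlen <- calls$svlen[tp_c]
  } else {
    tp$call_id <- character(); tp$call_pos <- integer(); tp$call_svlen <- integer()
  }
  fn <- truth[setdiff(seq_len(nrow(truth)), tp_t), , drop = FALSE]
  fp <- calls[setdiff(seq_len(nrow(calls)), tp_c), , drop = FALSE]
  structure(list(tp = tp, fn = fn, fp = fp, params = params),
            class = "variant_comparison")
}

rate_or_na <- function(num, denom) ifelse(denom > 0, num / denom, NA_real_)

#' Stratify a comparison by variant type and size bin
#'
#' Truth-derived records (TP, FN) are binned by the truth size; FP records
#' by the call size. Marginal rows carry `"ALL"` in the collapsed
#' dimension; the grand total row has both set to `"ALL"`. `tpr` is `NA`
#' when a cell holds no truth, `ppv` is `NA` when it holds no calls; F1
#' follows [f1_score()].
#'
#' @param result A `variant_comparison`.
#' @param bins Size-bin tibble as from [default_size_bins()].
#' @return Tibble with `type`, `bin`, `tp`, `fn`, `fp`, `tpr`, `ppv`,
#'   `f1`.
#' @export
stratify <- function(result, bins = default_size_bins()) {
  validate_bins(bins)
  tag <- function(v) {
    if (nrow(v) == 0L) {
      return(tibble::tibble(type = character(), bin = character()))
    }
    tibble::tibble(type = v$var_type, bin = assign_bin(v, bins))
  }
  counts <- dplyr::bind_rows(
    dplyr::mutate(tag(result$tp), what = "tp"),
    dplyr::mutate(tag(result$fn), what = "fn"),
    dplyr::mutate(tag(result$fp), what = "fp")
  )
  if (nrow(counts) == 0L) {
    return(tibble::tibble(type = "ALL", bin = "ALL", tp = 0L, fn = 0L,
                          fp = 0L, tpr = NA_real_, ppv = NA_real_, f1 = NA_real_))
  }
  cell_of <- function(df) {
    out <- df |>
      dplyr::count(.data$type, .data$bin, .data$what) |>
      tidyr::pivot_wider(names_from = "what", values_from = "n",
                         values_fill = 0L)
    for (col in c("tp", "fn", "fp")) if (!col %in% names(out)) out[[col]] <- 0L
    out
  }
  cells <- cell_of(counts)
  by_type <- cell_of(dplyr::mutate(counts, bin = "ALL"))
  by_bin <- cell_of(dplyr::mutate(counts, type = "ALL"))
  total <- cell_of(dplyr::mutate(counts, type = "ALL", bin = "ALL"))
  out <- dplyr::bind_rows(cells, by_type, by_bin, total)
  out$tpr <- rate_or_na(out$tp, out$tp + out$fn)
  out$ppv <- rate_or_na(out$tp, out$tp + out$fp)
  out$f1 <- f1_score(out$tpr, out$ppv)
  bin_order <- c(bins$label[order(bins$lo)], "ALL")
  dplyr::arrange(out, .data$type == "ALL", .data$type,
                 match(.data$bin, bin_order))[, c("type", "bin", "tp", "fn",
                                                  "fp", "tpr", "ppv", "f1")]
}

#' @export
print.variant_comparison <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("Variant comparison: %d TP, %d FN, %d FP (TPR %.4f, PPV %.4f, F1 %.4f)\n",
              g$tp, g$fn, g$fp, g$tpr, g$ppv, g$f1))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.variant_comparison <- function(x, bins = default_size_bins(), ...) {
  stratify(x, bins)
}

#' @exportS3Method generics::glance
glance.variant_comparison <- function(x, ...) {
  tp <- nrow(x$tp); fn <- nrow(x$fn); fp <- nrow(x$fp)
  tpr <- rate_or_na(tp, tp + fn); ppv <- rate_or_na(tp, tp + fp)
  tibble::tibble(tp = tp, fn = fn, fp = fp, tpr = tpr, ppv = ppv,
                 f1 = f1_score(tpr, ppv))
}

#' Write a variant comparison report as JSON
#'
#' Versioned schema: matching parameters, bin definitions, per
#' `(type, bin)` cells with counts and rates, and the grand totals.
#'
#' @param result A `variant_comparison`.
#' @param path Output path.
#' @param bins Size-bin tibble.
#' @return `path`, invisibly.
#' @export
write_variant_report_json <- function(result, path, bins = default_size_bins()) {
  cells <- stratify(result, bins)
  obj <- list(
    schema = "simval_variant_report",
    version = 1L,
    params = unclass(result$params),
    bins = bins[order(bins$lo), ],
    cells = cells[cells$type != "ALL" & cells$bin != "ALL", ],
    totals = as.list(glance(result))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
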