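# Alignment validation: score a SAM/BAM against the truth encoded in read
# names, overall and restricted to region types.

VERDICTS <- c("CORRECT", "INCORRECT_POS", "INCORRECT_CHROM", "UNMAPPED",
              "UNKNOWN_READ")

#' Is an alignment close to any true location?
#'
#' An alignment is correct when some alternative true location has the same
#' reference contig and an anchor within `wiggle` bp of the reported
#' leftmost aligned position (soft-clips excluded). Strand is deliberately
#' not compared: near clipped anchors aligners may legitimately report
#' either orientation.
#'
#' @param contig,pos0 Reported contig and 0-based leftmost aligned
#'   position.
#' @param alts Alternatives table: parallel vectors `ref_contig`,
#'   `anchor0`, ... as produced by [true_alignments()].
#' @param wiggle Tolerance in bp (>= 0).
#' @return List with `correct` (logical) and `matched` (index of the first
#'   matching alternative, or `NA`), plus `same_chrom` (any alternative on
#'   the reported contig).
#' @export
is_correct <- function(contig, pos0, alts, wiggle = 20L) {
  same <- alts$ref_contig == contig
  hit <- same & abs(alts$anchor0 - pos0) <= wiggle
  list(correct = any(hit),
       matched = if (any(hit)) which(hit)[1] else NA_integer_,
       same_chrom = any(same))
}

# read a SAM or BAM into a plain tibble of records
read_alignment_records <- function(path) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    path <- Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                             indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(what = c("qname", "flag", "rname", "pos", "mapq"))
  x <- Rsamtools::scanBam(Rsamtools::BamFile(path), param = p)[[1]]
  tibble::tibble(
    qname = x$qname, flag = x$flag,
    rname = as.character(x$rname), pos = x$pos, mapq = x$mapq
  )
}

#' Validate aligned reads against encoded truth
#'
#' Scores every primary record of a SAM/BAM: reads whose names decode to a
#' truth record are CORRECT / INCORRECT_POS / INCORRECT_CHROM / UNMAPPED;
#' undecodable names become UNKNOWN_READ and are excluded from the accuracy
#' denominator. A record is CORRECT when it is close to any true location
#' of either mate; the matched mate is recorded from the payload, so
#' aligner mate-swapping cannot corrupt scoring. Secondary and
#' supplementary records are counted but never judged. Per-region
#' categories tally each record under every region label it touches, so
#' one record may count in several categories.
#'
#' @param path SAM or BAM file (any sort order).
#' @param wiggle Position tolerance in bp.
#' @param sidecar Optional truth sidecar tibble for overflow names.
#' @return An `alignment_report`: list with `summary` (tibble: `category`,
#'   `n`, per-verdict counts, `fraction_correct`), `verdicts` (per-record
#'   tibble), and `n_secondary`.
#' @export
validate_alignments <- function(path, wiggle = 20L, sidecar = NULL) {
  recs <- read_alignment_records(path)
  secondary <- bitwAnd(recs$flag, 0x100L) > 0L | bitwAnd(recs$flag, 0x800L) > 0L
  n_secondary <- sum(secondary)
  recs <- recs[!secondary, , drop = FALSE]
  n <- nrow(recs)
  verdict <- character(n); matched <- rep(NA_integer_, n)
  read_id <- rep(NA_character_, n); mate <- rep(NA_integer_, n)
  labels <- rep(NA_character_, n)
  cache <- new.env(parent = emptyenv())
  for (i in seq_len(n)) {
    qn <- recs$qname[i]
    tr <- if (exists(qn, cache, inherits = FALSE)) get(qn, cache) else {
      x <- tryCatch(decode_truth(qn, sidecar), error = function(e) e)
      assign(qn, x, cache)
      x
    }
    if (inherits(tr, "error")) {
      verdict[i] <- "UNKNOWN_READ"
      next
    }
    read_id[i] <- tr$read_id
    union_labels <- unique(c(tr$mates[[1]]$labels, tr$mates[[2]]$labels))
    if (bitwAnd(recs$flag[i], 0x4L) > 0L || is.na(recs$pos[i])) {
      verdict[i] <- "UNMAPPED"
      labels[i] <- paste(union_labels, collapse = ",")
      next
    }
    hit <- FALSE; same_chrom <- FALSE
    for (m in 1:2) {
      chk <- is_correct(recs$rname[i], recs$pos[i] - 1L, tr$mates[[m]]$alts,
                        wiggle)
      same_chrom <- same_chrom || chk$same_chrom
      if (chk$correct) {
        hit <- TRUE
        mate[i] <- m
        matched[i] <- chk$matched
        labels[i] <- paste(tr$mates[[m]]$labels, collapse = ",")
        break
      }
    }
    if (hit) {
      verdict[i] <- "CORRECT"
    } else {
      labels[i] <- paste(union_labels, collapse = ",")
      verdict[i] <- if (same_chrom) "INCORRECT_POS" else "INCORRECT_CHROM"
    }
  }
  verdicts <- tibble::tibble(read_id = read_id, mate = mate, verdict = verdict,
                             matched_alt = matched, mapq = recs$mapq,
                             labels = labels)
  summary <- summarize_verdicts(verdicts)
  structure(list(summary = summary, verdicts = verdicts,
                 n_secondary = n_secondary, wiggle = wiggle),
            class = "alignment_report")
}

summarize_verdicts <- function(verdicts) {
  categories <- c("ALL", sort(unique(unlist(
    strsplit(verdicts$labels[!is.na(verdicts$labels)], ",", fixed = TRUE)
  ))))
  rows <- lapply(categories, function(cat) {
    sel <- if (cat == "ALL") rep(TRUE, nrow(verdicts)) else {
      !is.na(verdicts$labels) &
        vapply(strsplit(verdicts$labels, ",", fixed = TRUE),
               function(l) cat %in% l, logical(1))
    }
    v <- verdicts$verdict[sel]
    counts <- table(factor(v, levels = VERDICTS))
    denom <- sum(sel) - counts[["UNKNOWN_READ"]]
    tibble::tibble(
      category = cat, n = sum(sel),
      correct = counts[["CORRECT"]],
      incorrect_pos = counts[["INCORRECT_POS"]],
      incorrect_chrom = counts[["INCORRECT_CHROM"]],
      unmapped = counts[["UNMAPPED"]],
      unknown = counts[["UNKNOWN_READ"]],
      fraction_correct = if (denom > 0) counts[["CORRECT"]] / denom else NA_real_
    )
  })
  dplyr::bind_rows(rows)
}

#' @export
print.alignment_report <- function(x, ...) {
  cat("Alignment validation (wiggle = ", x$wiggle, " bp)\n", sep = "")
  print(x$summary)
  if (x$n_secondary > 0) {
    cat(x$n_secondary, "secondary/supplementary records ignored\n")
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.alignment_report <- function(x, ...) x$summary

#' @exportS3Method generics::glance
glance.alignment_report <- function(x, ...) {
  all <- x$summary[x$summary$category == "ALL", , drop = FALSE]
  tibble::tibble(n = all$n, fraction_correct = all$fraction_correct,
                 n_secondary = x$n_secondary, wiggle = x$wiggle)
}

#' Write an alignment report as JSON
#'
#' Versioned schema: categories with verdict counts and
#' `fraction_correct`.
#'
#' @param report An `alignment_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment_report_json <- function(report, path) {
  obj <- list(
    schema = "simval_alignment_report",
    version = 1L,
    wiggle = report$wiggle,
    n_secondary = report$n_secondary,
    categories = report$summary
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Write truth records as a perfect SAM
#'
#' Converts each read's first true alternative into a primary SAM record
#' (anchor as the leftmost aligned position). Feeding the result to
#' [validate_alignments()] must give `fraction_correct == 1` in every
#' category; it also serves as an idealized "perfect aligner" baseline.
#'
#' @param reads Annotated reads tibble from [simulate_reads()].
#' @param reference Named character vector or DNAStringSet (for `@SQ`
#'   lines).
#' @param path Output SAM path.
#' @param shift_by Optional constant added to every position (useful for
#'   constructing deliberately wrong alignments).
#' @param unmapped Emit every record as unmapped instead.
#' @return `path`, invisibly.
#' @export
write_truth_sam <- function(reads, reference, path, shift_by = 0L,
                            unmapped = FALSE) {
  reference <- ref_as_character(reference)
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              paste0("@SQ\tSN:", names(reference), "\tLN:", nchar(reference)))
  lines <- character(nrow(reads))
  for (i in seq_len(nrow(reads))) {
    a <- reads$alts[[i]]
    mate_flag <- if (reads$mate[i] == 1L) 0x40L else 0x80L
    if (unmapped) {
      lines[i] <- paste(reads$name[i], bitwOr(bitwOr(4L, 1L), mate_flag), "*",
                        0L, 0L, "*", "*", 0L, 0L,
                        reads$seq[i], reads$qual[i], sep = "\t")
    } else {
      flag <- bitwOr(bitwOr(1L, mate_flag), if (a$strand[1] == "-") 16L else 0L)
      alen <- min(a$alen[1], nchar(reads$seq[i]))
      cig <- paste0(alen, "M",
                    if (alen < nchar(reads$seq[i])) {
                      paste0(nchar(reads$seq[i]) - alen, "S")
                    } else "")
      lines[i] <- paste(reads$name[i], flag, a$ref_contig[1],
                        a$anchor0[1] + 1L + shift_by, 60L, cig, "*", 0L, 0L,
                        reads$seq[i], reads$qual[i], sep = "\t")
    }
  }
  writeLines(c(header, lines), path)
  invisible(path)
}
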