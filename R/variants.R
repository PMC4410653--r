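# Variant data model, VCF reading/writing and canonical normalization.
#
# A variant set is an ordinary tibble with one row per ALT allele:
#   chrom      reference contig name
#   pos        1-based VCF position (first affected base for SNV/MNP,
#              anchor base for indels and symbolic SVs)
#   id         stable record id
#   ref        REF allele (anchor base only for symbolic ALTs)
#   alt        ALT allele: sequence, or <DEL>, <INS>, <INV>, <DUP:TANDEM>
#   var_type   one of SNV, MNP, INS, DEL, INV, DUP
#   svlen      signed length change in bp (0 for SNV/MNP, span for INV)
#   ins_seq    concrete inserted sequence (NA when unresolved)
#   dup_copies total tandem copy count for DUP (>= 2)
#   gt1, gt2   phased per-haplotype presence (0/1)
#
# All interface coordinates are 1-based inclusive (VCF convention); internal
# interval arithmetic is 0-based half-open.

VAR_TYPES <- c("SNV", "MNP", "INS", "DEL", "INV", "DUP")

#' Construct an empty variant table
#'
#' Returns a zero-row tibble with the canonical variant columns and types.
#' Useful as a starting point when building variant sets programmatically.
#'
#' @return A tibble with columns `chrom`, `pos`, `id`, `ref`, `alt`,
#'   `var_type`, `svlen`, `ins_seq`, `dup_copies`, `gt1`, `gt2`.
#' @export
variant_tbl <- function() {
  tibble::tibble(
    chrom = character(), pos = integer(), id = character(),
    ref = character(), alt = character(), var_type = character(),
    svlen = integer(), ins_seq = character(), dup_copies = integer(),
    gt1 = integer(), gt2 = integer()
  )
}

# coerce a data frame with at least chrom/pos/ref/alt/gt columns into the
# canonical column set, filling derivable fields
as_variant_tbl <- function(df) {
  tpl <- variant_tbl()
  for (col in names(tpl)) {
    if (!col %in% names(df)) df[[col]] <- rep(tpl[[col]][NA_integer_], nrow(df))
  }
  df$pos <- as.integer(df$pos)
  df$svlen <- as.integer(df$svlen)
  df$dup_copies <- as.integer(df$dup_copies)
  df$gt1 <- as.integer(df$gt1)
  df$gt2 <- as.integer(df$gt2)
  tibble::as_tibble(df[, names(tpl)])
}

# reference accessor: accept DNAStringSet or named character vector and
# return a named character vector of contig sequences
ref_as_character <- function(reference) {
  if (methods::is(reference, "DNAStringSet")) {
    out <- as.character(reference)
    names(out) <- sub("\\s.*$", "", names(reference))
    return(out)
  }
  if (is.character(reference) && !is.null(names(reference))) {
    return(reference)
  }
  stop("`reference` must be a named character vector or a DNAStringSet", call. = FALSE)
}

ref_fetch <- function(reference, chrom, start1, end1) {
  substr(reference[[chrom]], start1, end1)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Read a FASTA file into a named character vector
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] that strips
#' description text from sequence names.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  ref_as_character(Biostrings::readDNAStringSet(path))
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector (or DNAStringSet) of sequences.
#' @param path Output path; lines are wrapped at 60 columns.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (!methods::is(seqs, "DNAStringSet")) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path, width = 60L)
  invisible(path)
}

# ---- type classification and spans ---------------------------------------

SYMBOLIC_TYPES <- c("<DEL>" = "DEL", "<INS>" = "INS", "<INV>" = "INV",
                    "<DUP>" = "DUP", "<DUP:TANDEM>" = "DUP")

is_symbolic_alt <- function(alt) grepl("^<.*>$", alt)

classify_alleles <- function(ref, alt) {
  nr <- nchar(ref); na <- nchar(alt)
  dplyr::case_when(
    nr == 1L & na == 1L ~ "SNV",
    nr == na ~ "MNP",
    nr < na ~ "INS",
    TRUE ~ "DEL"
  )
}

# 0-based half-open reference footprint (anchor base included) used for
# overlap / gap checks
variant_footprint <- function(v) {
  start0 <- v$pos - 1L
  end0 <- start0 + dplyr::case_when(
    v$var_type %in% c("SNV", "MNP") ~ nchar(v$ref),
    v$var_type == "INS" ~ 1L,
    v$var_type == "DEL" ~ abs(v$svlen) + 1L,
    v$var_type %in% c("INV", "DUP") ~ v$svlen + 1L
  )
  tibble::tibble(start0 = start0, end0 = as.integer(end0))
}

# 0-based half-open interval of reference bases whose content changes on the
# host haplotype (excludes the anchor for indels/SVs)
variant_edit_span <- function(v) {
  s <- integer(nrow(v)); e <- integer(nrow(v))
  for (i in seq_len(nrow(v))) {
    p0 <- v$pos[i] - 1L
    switch(v$var_type[i],
      SNV = , MNP = { s[i] <- p0; e[i] <- p0 + nchar(v$ref[i]) },
      INS = { s[i] <- p0 + 1L; e[i] <- p0 + 1L },
      DEL = { s[i] <- p0 + 1L; e[i] <- p0 + 1L + abs(v$svlen[i]) },
      INV = , DUP = { s[i] <- p0 + 1L; e[i] <- p0 + 1L + v$svlen[i] }
    )
  }
  tibble::tibble(start0 = s, end0 = e)
}

#' Validate a variant table against a reference
#'
#' Checks the structural invariants of the variant model: coordinates inside
#' the contig, type-consistent `svlen` signs, single differing bases for
#' SNVs, REF alleles that match the reference sequence, and at least one
#' non-reference haplotype per record.
#'
#' @param variants Variant tibble.
#' @param reference Named character vector or DNAStringSet.
#' @return `variants`, invisibly; errors describe the first offending record.
#' @export
validate_variants <- function(variants, reference) {
  reference <- ref_as_character(reference)
  v <- variants
  for (i in seq_len(nrow(v))) {
    lab <- sprintf("variant %s (%s:%d)", v$id[i], v$chrom[i], v$pos[i])
    if (!v$chrom[i] %in% names(reference)) stop(lab, ": unknown contig", call. = FALSE)
    if (is.na(v$pos[i]) || v$pos[i] < 1L) stop(lab, ": pos < 1", call. = FALSE)
    fp <- variant_footprint(v[i, ])
    if (fp$end0 > nchar(reference[[v$chrom[i]]])) {
      stop(lab, ": extends beyond contig end", call. = FALSE)
    }
    if (!v$var_type[i] %in% VAR_TYPES) stop(lab, ": unknown var_type", call. = FALSE)
    if (v$var_type[i] == "SNV" &&
        (nchar(v$ref[i]) != 1L || nchar(v$alt[i]) != 1L || v$ref[i] == v$alt[i])) {
      stop(lab, ": SNV alleles must be single, different bases", call. = FALSE)
    }
    if (v$var_type[i] == "DEL" && v$svlen[i] >= 0L) stop(lab, ": DEL needs svlen < 0", call. = FALSE)
    if (v$var_type[i] %in% c("INS", "DUP", "INV") && v$svlen[i] <= 0L) {
      stop(lab, ": ", v$var_type[i], " needs svlen > 0", call. = FALSE)
    }
    if (v$var_type[i] == "DUP" && (is.na(v$dup_copies[i]) || v$dup_copies[i] < 2L)) {
      stop(lab, ": DUP needs dup_copies >= 2", call. = FALSE)
    }
    if (!is_symbolic_alt(v$alt[i])) {
      seen <- ref_fetch(reference, v$chrom[i], v$pos[i], v$pos[i] + nchar(v$ref[i]) - 1L)
      if (toupper(seen) != toupper(v$ref[i])) {
        stop(lab, ": REF allele does not match reference (", seen, ")", call. = FALSE)
      }
    }
    if ((v$gt1[i] + v$gt2[i]) == 0L) stop(lab, ": genotype 0|0 not allowed", call. = FALSE)
  }
  invisible(variants)
}

# ---- normalization --------------------------------------------------------

# left-align + trim one explicit-allele variant; returns list(pos, ref, alt)
normalize_alleles <- function(chrom, pos, ref, alt, reference) {
  ctg <- reference[[chrom]]
  if (identical(ref, alt)) stop("identity record (REF == ALT) at ", chrom, ":", pos, call. = FALSE)
  repeat {
    nr <- nchar(ref); na <- nchar(alt)
    if (nr > 0L && na > 0L) {
      lr <- substr(ref, nr, nr); la <- substr(alt, na, na)
      if (lr == la) {
        ref <- substr(ref, 1L, nr - 1L)
        alt <- substr(alt, 1L, na - 1L)
        next
      }
      break
    }
    # one allele empty: extend to the left, or anchor on the right at pos 1
    if (pos > 1L) {
      pos <- pos - 1L
      b <- substr(ctg, pos, pos)
      ref <- paste0(b, ref)
      alt <- paste0(b, alt)
    } else {
      b <- substr(ctg, pos + nchar(ref), pos + nchar(ref))
      ref <- paste0(ref, b)
      alt <- paste0(alt, b)
      break
    }
  }
  # trim shared leading bases, keeping the single anchor base for indels
  repeat {
    nr <- nchar(ref); na <- nchar(alt)
    if (nr > 1L && na > 1L && substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
      ref <- substr(ref, 2L, nr)
      alt <- substr(alt, 2L, na)
      pos <- pos + 1L
    } else break
  }
  if (identical(ref, alt)) stop("identity record (REF == ALT) at ", chrom, ":", pos, call. = FALSE)
  list(pos = pos, ref = ref, alt = alt)
}

#' Normalize variants to canonical form
#'
#' Trims shared leading/trailing bases (keeping the single VCF anchor base
#' for indels) and left-aligns indels to the smallest position that yields an
#' identical edited sequence. Symbolic SV records (`<DEL>`, `<INS>`, `<INV>`,
#' `<DUP:TANDEM>`) are position-anchored already and pass through unchanged.
#' The operation is idempotent and preserves the implied edited sequence.
#'
#' @param variants Variant tibble.
#' @param reference Named character vector or DNAStringSet.
#' @return Normalized variant tibble, same row order.
#' @export
normalize_variants <- function(variants, reference) {
  reference <- ref_as_character(reference)
  v <- variants
  for (i in seq_len(nrow(v))) {
    if (is_symbolic_alt(v$alt[i])) next
    nz <- normalize_alleles(v$chrom[i], v$pos[i], v$ref[i], v$alt[i], reference)
    v$pos[i] <- nz$pos
    v$ref[i] <- nz$ref
    v$alt[i] <- nz$alt
    v$var_type[i] <- classify_alleles(nz$ref, nz$alt)
    v$svlen[i] <- nchar(nz$alt) - nchar(nz$ref)
    if (v$var_type[i] %in% c("SNV", "MNP")) v$svlen[i] <- 0L
    # keep ins_seq consistent with the (possibly shifted) canonical alleles
    v$ins_seq[i] <- if (v$var_type[i] == "INS") {
      substr(nz$alt, nchar(nz$ref) + 1L, nchar(nz$alt))
    } else NA_character_
  }
  v
}

# ---- size bins ------------------------------------------------------------

#' Default variant size bins
#'
#' Disjoint bins covering sizes 1 bp to infinity, used to stratify
#' sensitivity and precision by variant size. SNVs always fall in the first
#' bin.
#'
#' @return Tibble with columns `label`, `lo`, `hi` (`hi = Inf` for the open
#'   top bin); bounds are inclusive.
#' @export
default_size_bins <- function() {
  lo <- c(1, 2, 6, 21, 51, 101, 201, 501, 1001, 2001, 5001)
  hi <- c(1, 5, 20, 50, 100, 200, 500, 1000, 2000, 5000, Inf)
  tibble::tibble(
    label = ifelse(is.infinite(hi), paste0(">", lo - 1),
                   ifelse(lo == hi, as.character(lo), paste0(lo, "-", hi))),
    lo = lo, hi = hi
  )
}

validate_bins <- function(bins) {
  stopifnot(all(bins$lo <= bins$hi))
  o <- order(bins$lo)
  lo <- bins$lo[o]; hi <- bins$hi[o]
  if (lo[1] != 1 || !is.infinite(hi[length(hi)]) ||
      any(lo[-1] != hi[-length(hi)] + 1)) {
    stop("size bins must be disjoint and cover [1, Inf)", call. = FALSE)
  }
  invisible(bins)
}

# size used for binning: SNV counts as 1, MNP as its length
variant_bin_size <- function(v) {
  ifelse(v$var_type == "SNV", 1L,
         ifelse(v$var_type == "MNP", nchar(v$ref), abs(v$svlen)))
}

#' Assign variants to size bins
#'
#' Maps each variant to the unique bin containing its size (`|svlen|`; SNVs
#' count as size 1, MNPs as their length).
#'
#' @param variants Variant tibble.
#' @param bins Bin tibble as from [default_size_bins()].
#' @return Character vector of bin labels, one per variant.
#' @export
assign_bin <- function(variants, bins = default_size_bins()) {
  validate_bins(bins)
  size <- variant_bin_size(variants)
  o <- order(bins$lo)
  idx <- findInterval(size, bins$lo[o])
  bins$label[o][idx]
}

# ---- VCF I/O --------------------------------------------------------------

parse_gt <- function(gt, allele_index) {
  # returns c(gt1, gt2) presence of `allele_index` on each haplotype;
  # "." treated as 0
  parts <- strsplit(sub(":.*$", "", gt), "[|/]")[[1]]
  if (length(parts) == 1L) parts <- c(parts, parts)
  a <- suppressWarnings(as.integer(parts))
  a[is.na(a)] <- 0L
  as.integer(a[1:2] == allele_index)
}

extract_info_field <- function(info, key) {
  m <- regmatches(info, regexpr(paste0("(?:^|;)", key, "=([^;]+)"), info))
  if (length(m) == 0L) return(NA_character_)
  sub(paste0("^;?", key, "="), "", m)
}

#' Read a VCF file into a variant tibble
#'
#' Parses a single-sample VCF 4.x (plain or gzipped) via
#' [vcfR::read.vcfR()], decomposes multi-allelic records into one row per
#' ALT allele, resolves symbolic SV lengths from `SVLEN`/`END`, drops
#' records with genotype `0|0` or on unknown contigs (with a warning), and
#' normalizes every record. Output rows are sorted by `(chrom, pos)`.
#'
#' @param path VCF file path.
#' @param reference Named character vector or DNAStringSet.
#' @param mode `"lenient"` (default) skips unresolvable records with a
#'   warning; `"strict"` aborts on them.
#' @return Normalized variant tibble.
#' @export
read_vcf <- function(path, reference, mode = c("lenient", "strict")) {
  mode <- match.arg(mode)
  reference <- ref_as_character(reference)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf, getINFO = TRUE)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  n_header <- length(vcf@meta) + 1L  # meta lines plus #CHROM line
  gt_mat <- if (!is.null(vcf@gt) && ncol(vcf@gt) >= 2L) vcf@gt[, 2L, drop = TRUE] else rep("1|1", nrow(fix))

  rows <- vector("list", nrow(fix))
  for (i in seq_len(nrow(fix))) {
    line_no <- n_header + i
    chrom <- fix[i, "CHROM"]; pos <- suppressWarnings(as.integer(fix[i, "POS"]))
    ref <- fix[i, "REF"]; alt_field <- fix[i, "ALT"]; info <- fix[i, "INFO"]
    rid <- fix[i, "ID"]
    if (is.na(rid) || rid == ".") rid <- sprintf("var_%s_%s", chrom, fix[i, "POS"])
    if (is.na(pos) || is.na(ref) || is.na(alt_field) || alt_field == ".") {
      stop("malformed VCF record at line ", line_no, call. = FALSE)
    }
    if (!chrom %in% names(reference)) {
      warning("line ", line_no, ": unknown contig ", chrom, ", record skipped", call. = FALSE)
      next
    }
    gt <- if (length(gt_mat) >= i && !is.na(gt_mat[i])) gt_mat[i] else "1|1"
    alts <- strsplit(alt_field, ",", fixed = TRUE)[[1]]
    sub_rows <- vector("list", length(alts))
    for (k in seq_along(alts)) {
      alt <- alts[k]
      g <- parse_gt(gt, k)
      if (sum(g) == 0L) {
        if (length(alts) == 1L) {
          warning("line ", line_no, ": genotype 0|0, record skipped", call. = FALSE)
        }
        next
      }
      row <- tryCatch(
        parse_one_alt(chrom, pos, rid, ref, alt, info, g, length(alts) > 1L, k),
        error = function(e) e
      )
      if (inherits(row, "error")) {
        msg <- paste0("line ", line_no, ": ", conditionMessage(row))
        if (mode == "strict") stop(msg, call. = FALSE)
        warning(msg, ", record skipped", call. = FALSE)
        next
      }
      sub_rows[[k]] <- row
    }
    rows[[i]] <- dplyr::bind_rows(sub_rows)
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) return(variant_tbl())
  out <- as_variant_tbl(out)
  out <- normalize_variants(out, reference)
  validate_variants(out, reference)
  dplyr::arrange(out, .data$chrom, .data$pos, .data$id)
}

parse_one_alt <- function(chrom, pos, rid, ref, alt, info, g, multi, k) {
  # matrix extraction upstream leaves names attributes behind; strip them
  chrom <- unname(chrom); ref <- unname(ref); alt <- unname(alt)
  info <- unname(info); rid <- unname(rid)
  id <- if (multi) paste0(rid, "_", k) else rid
  if (is_symbolic_alt(alt)) {
    if (!alt %in% names(SYMBOLIC_TYPES)) stop("unsupported symbolic ALT ", alt)
    var_type <- SYMBOLIC_TYPES[[alt]]
    svlen_s <- extract_info_field(info, "SVLEN")
    end_s <- extract_info_field(info, "END")
    svlen <- suppressWarnings(as.integer(svlen_s))
    if (is.na(svlen) && !is.na(end_s)) {
      span <- as.integer(end_s) - pos
      svlen <- if (var_type == "DEL") -span else span
    }
    if (is.na(svlen)) stop("symbolic ALT ", alt, " without resolvable SVLEN/END")
    if (var_type == "DEL" && svlen > 0L) svlen <- -svlen
    if (var_type != "DEL") svlen <- abs(svlen)
    dup_copies <- NA_integer_
    if (var_type == "DUP") {
      cn <- suppressWarnings(as.integer(extract_info_field(info, "DUPCOPIES")))
      dup_copies <- if (is.na(cn)) 2L else cn
    }
    ins_seq <- if (var_type == "INS") extract_info_field(info, "INSSEQ") else NA_character_
    tibble::tibble(
      chrom = chrom, pos = pos, id = id, ref = substr(ref, 1, 1), alt = alt,
      var_type = var_type, svlen = svlen, ins_seq = ins_seq,
      dup_copies = dup_copies, gt1 = g[1], gt2 = g[2]
    )
  } else {
    if (!grepl("^[ACGTNacgtn]+$", alt)) stop("unparseable ALT allele ", alt)
    var_type <- classify_alleles(ref, alt)
    tibble::tibble(
      chrom = chrom, pos = pos, id = id, ref = toupper(ref), alt = toupper(alt),
      var_type = var_type,
      svlen = ifelse(var_type %in% c("SNV", "MNP"), 0L, nchar(alt) - nchar(ref)),
      ins_seq = ifelse(var_type == "INS",
                       substr(toupper(alt), nchar(ref) + 1L, nchar(alt)), NA_character_),
      dup_copies = NA_integer_, gt1 = g[1], gt2 = g[2]
    )
  }
}

format_vcf_record <- function(v) {
  info <- character(nrow(v))
  for (i in seq_len(nrow(v))) {
    if (is_symbolic_alt(v$alt[i])) {
      fields <- c(
        paste0("SVTYPE=", v$var_type[i]),
        paste0("SVLEN=", v$svlen[i]),
        paste0("END=", v$pos[i] + abs(v$svlen[i]))
      )
      if (!is.na(v$dup_copies[i])) fields <- c(fields, paste0("DUPCOPIES=", v$dup_copies[i]))
      if (!is.na(v$ins_seq[i])) fields <- c(fields, paste0("INSSEQ=", v$ins_seq[i]))
      info[i] <- paste(fields, collapse = ";")
    } else {
      info[i] <- "."
    }
  }
  paste(v$chrom, v$pos, v$id, v$ref, v$alt, ".", "PASS", info, "GT",
        paste0(v$gt1, "|", v$gt2), sep = "\t")
}

#' Write a variant tibble as a VCF 4.2 file
#'
#' Emits a single-sample VCF with phased genotypes. Symbolic SVs carry
#' `SVTYPE`, `SVLEN`, `END` (and `DUPCOPIES`/`INSSEQ` where set) in INFO so
#' that [read_vcf()] reproduces the table record for record.
#'
#' @param variants Variant tibble, sorted by `(chrom, pos)`.
#' @param path Output path.
#' @param contigs Named integer vector of contig lengths for the header, or
#'   a reference (named character / DNAStringSet) from which lengths are
#'   taken.
#' @param sample Sample name for the genotype column.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, path, contigs, sample = "SIM") {
  if (!is.numeric(contigs)) {
    r <- ref_as_character(contigs)
    contigs <- stats::setNames(nchar(r), names(r))
  }
  v <- variants
  if (nrow(v) > 1L) {
    o <- order(v$chrom, v$pos)
    if (!identical(o, seq_len(nrow(v)))) stop("variants must be sorted by (chrom, pos)", call. = FALSE)
  }
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=simval",
    paste0("##contig=<ID=", names(contigs), ",length=", contigs, ">"),
    '##INFO=<ID=SVTYPE,Number=1,Type=String,Description="SV type">',
    '##INFO=<ID=SVLEN,Number=1,Type=Integer,Description="Signed SV length">',
    '##INFO=<ID=END,Number=1,Type=Integer,Description="End position of SV">',
    '##INFO=<ID=DUPCOPIES,Number=1,Type=Integer,Description="Total tandem copy count">',
    '##INFO=<ID=INSSEQ,Number=1,Type=String,Description="Resolved insertion sequence">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample, sep = "\t")
  )
  body <- if (nrow(v) > 0L) format_vcf_record(v) else character()
  writeLines(c(header, body), path)
  invisible(path)
}
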