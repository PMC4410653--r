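# Diploid genome construction and the perturbed<->reference block map.
#
# The map is a tibble of blocks, one row per block:
#   host_contig, host_start (0-based), host_len,
#   ref_contig,  ref_start  (0-based), ref_len,
#   strand ("+"/"-"), feature (SEQ, INS_NOVEL, DEL_GAP, INV, DUP_COPY),
#   variant_id (NA for plain SEQ blocks)
#
# Within a host contig the blocks with host_len > 0 tile [0, contig length)
# exactly; DEL_GAP blocks occupy zero host width at their join point. The
# map is single-valued host -> reference: a duplicated base lifts to its one
# source interval.

MAP_FEATURES <- c("SEQ", "INS_NOVEL", "DEL_GAP", "INV", "DUP_COPY")

map_block_tbl <- function() {
  tibble::tibble(
    host_contig = character(), host_start = integer(), host_len = integer(),
    ref_contig = character(), ref_start = integer(), ref_len = integer(),
    strand = character(), feature = character(), variant_id = character()
  )
}

#' Apply phased variants to one reference contig
#'
#' Edits the reference left to right: SNV/MNP substitute in place inside a
#' SEQ block; DEL removes its span and records a zero-width DEL_GAP; INS
#' splices in `ins_seq` and records an INS_NOVEL block; INV replaces its
#' span by the reverse complement (strand `-`); a tandem DUP with `c`
#' copies keeps the original span in the SEQ flow and appends `c - 1`
#' DUP_COPY blocks that reference the same source interval.
#'
#' @param ref_seq Reference contig sequence (character scalar).
#' @param variants Variant tibble restricted to this contig and haplotype;
#'   must be normalized, sorted by position, with pairwise non-overlapping
#'   reference footprints.
#' @param ref_contig,host_contig Contig names recorded in the map blocks.
#' @return List with `seq` (host sequence) and `blocks` (map block tibble).
#' @export
build_haplotype <- function(ref_seq, variants, ref_contig = "ref",
                            host_contig = paste0(ref_contig, "_hap")) {
  v <- variants[order(variants$pos), , drop = FALSE]
  ref_len <- nchar(ref_seq)
  if (nrow(v) > 0L) {
    fp <- variant_footprint(v)
    if (any(fp$end0 > ref_len)) {
      bad <- v$id[which(fp$end0 > ref_len)[1]]
      stop("variant ", bad, " extends beyond contig end", call. = FALSE)
    }
    if (nrow(v) > 1L) {
      ov <- which(fp$start0[-1] < fp$end0[-nrow(v)])
      if (length(ov) > 0L) {
        stop("overlapping variants ", v$id[ov[1]], " and ", v$id[ov[1] + 1L],
             call. = FALSE)
      }
    }
  }

  pieces <- character(); blocks <- list()
  h0 <- 0L                 # next host coordinate
  run_start <- 0L          # 0-based ref start of the open SEQ run
  run_subs <- list()       # in-place substitutions within the open run
  r0 <- 0L                 # next unconsumed ref coordinate

  close_run <- function(run_end) {
    # emit SEQ block [run_start, run_end) with substitutions applied
    if (run_end > run_start) {
      piece <- substr(ref_seq, run_start + 1L, run_end)
      for (sb in run_subs) {
        off <- sb$pos0 - run_start
        substr(piece, off + 1L, off + nchar(sb$alt)) <- sb$alt
      }
      pieces[[length(pieces) + 1L]] <<- piece
      blocks[[length(blocks) + 1L]] <<- tibble::tibble(
        host_contig = host_contig, host_start = h0,
        host_len = run_end - run_start,
        ref_contig = ref_contig, ref_start = run_start,
        ref_len = run_end - run_start,
        strand = "+", feature = "SEQ", variant_id = NA_character_
      )
      h0 <<- h0 + (run_end - run_start)
    }
    run_subs <<- list()
  }
  add_block <- function(host_len, ref_start, ref_len, strand, feature, vid, piece = NULL) {
    if (!is.null(piece)) pieces[[length(pieces) + 1L]] <<- piece
    blocks[[length(blocks) + 1L]] <<- tibble::tibble(
      host_contig = host_contig, host_start = h0, host_len = as.integer(host_len),
      ref_contig = ref_contig, ref_start = as.integer(ref_start),
      ref_len = as.integer(ref_len), strand = strand, feature = feature,
      variant_id = vid
    )
    h0 <<- h0 + as.integer(host_len)
  }

  for (i in seq_len(nrow(v))) {
    ty <- v$var_type[i]
    if (ty %in% c("SNV", "MNP")) {
      run_subs[[length(run_subs) + 1L]] <- list(pos0 = v$pos[i] - 1L, alt = v$alt[i])
      next
    }
    es <- v$pos[i]  # 0-based start of the edited span (base after the anchor)
    if (ty == "DEL") {
      w <- abs(v$svlen[i])
      close_run(es)
      add_block(0L, es, w, "+", "DEL_GAP", v$id[i])
      run_start <- es + w; r0 <- run_start
    } else if (ty == "INS") {
      if (is.na(v$ins_seq[i])) stop("INS ", v$id[i], " has no resolved ins_seq", call. = FALSE)
      close_run(es)
      add_block(nchar(v$ins_seq[i]), es, 0L, "+", "INS_NOVEL", v$id[i],
                piece = v$ins_seq[i])
      run_start <- es
    } else if (ty == "INV") {
      w <- v$svlen[i]
      close_run(es)
      add_block(w, es, w, "-", "INV", v$id[i],
                piece = revcomp(substr(ref_seq, es + 1L, es + w)))
      run_start <- es + w
    } else if (ty == "DUP") {
      w <- v$svlen[i]
      close_run(es + w)  # original span stays in the SEQ flow
      span <- substr(ref_seq, es + 1L, es + w)
      for (k in seq_len(v$dup_copies[i] - 1L)) {
        add_block(w, es, w, "+", "DUP_COPY", v$id[i], piece = span)
      }
      run_start <- es + w
    }
  }
  close_run(ref_len)
  list(seq = paste(pieces, collapse = ""),
       blocks = dplyr::bind_rows(c(list(map_block_tbl()), blocks)))
}

#' Build a phased diploid genome plus its genome map
#'
#' Applies the phased truth set per contig and per haplotype via
#' [build_haplotype()]. Host contigs are named `<contig>_hapA` and
#' `<contig>_hapB`; homozygous variants appear in both haplotypes.
#'
#' @param reference Named character vector or DNAStringSet.
#' @param truth Phased, resolved variant tibble.
#' @return List with `haplotypes` (named character vector: all `_hapA`
#'   contigs then all `_hapB`), `map` (block tibble over both haplotypes),
#'   and `truth_hapA`/`truth_hapB` (the per-haplotype variant subsets).
#' @export
build_diploid <- function(reference, truth) {
  reference <- ref_as_character(reference)
  haps <- character(); maps <- list()
  for (hap in c("A", "B")) {
    gt <- if (hap == "A") truth$gt1 else truth$gt2
    for (ctg in names(reference)) {
      sel <- truth[gt == 1L & truth$chrom == ctg, , drop = FALSE]
      hb <- build_haplotype(reference[[ctg]], sel, ref_contig = ctg,
                            host_contig = paste0(ctg, "_hap", hap))
      haps[[paste0(ctg, "_hap", hap)]] <- hb$seq
      maps[[length(maps) + 1L]] <- hb$blocks
    }
  }
  list(
    haplotypes = haps,
    map = dplyr::bind_rows(maps),
    truth_hapA = truth[truth$gt1 == 1L, , drop = FALSE],
    truth_hapB = truth[truth$gt2 == 1L, , drop = FALSE]
  )
}

# internal: per-contig lookup structure for fast repeated lifts
map_index <- function(map) {
  split(map[order(map$host_start, -map$host_len), , drop = FALSE], map$host_contig)
}

consuming <- function(blocks) blocks[blocks$host_len > 0L, , drop = FALSE]

#' Lift one host position to the reference
#'
#' Binary-searches the block containing the position. SEQ and DUP_COPY
#' blocks lift by offset from `ref_start` (a duplicated base lifts to its
#' single source location); INV blocks mirror the offset (strand `-`);
#' positions inside a novel insertion return the insertion breakpoint with
#' feature `INS_NOVEL`.
#'
#' @param map Genome map tibble.
#' @param host_contig Host contig name.
#' @param host_pos 0-based host position.
#' @return One-row tibble: `ref_contig`, `ref_pos` (0-based), `strand`,
#'   `feature`.
#' @export
lift_point <- function(map, host_contig, host_pos) {
  blocks <- consuming(map[map$host_contig == host_contig, , drop = FALSE])
  if (nrow(blocks) == 0L) stop("unknown host contig ", host_contig, call. = FALSE)
  blocks <- blocks[order(blocks$host_start), , drop = FALSE]
  clen <- blocks$host_start[nrow(blocks)] + blocks$host_len[nrow(blocks)]
  if (host_pos < 0L || host_pos >= clen) {
    stop("host position ", host_pos, " outside [0, ", clen, ")", call. = FALSE)
  }
  i <- findInterval(host_pos, blocks$host_start)
  b <- blocks[i, ]
  off <- host_pos - b$host_start
  if (b$feature == "INS_NOVEL") {
    return(tibble::tibble(ref_contig = b$ref_contig, ref_pos = b$ref_start,
                          strand = "+", feature = "INS_NOVEL"))
  }
  if (b$feature == "INV") {
    return(tibble::tibble(ref_contig = b$ref_contig,
                          ref_pos = b$ref_start + b$host_len - 1L - off,
                          strand = "-", feature = "INV"))
  }
  tibble::tibble(ref_contig = b$ref_contig, ref_pos = b$ref_start + off,
                 strand = "+", feature = b$feature)
}

#' Lift a host interval to ordered reference segments
#'
#' Splits `[start0, end0)` at block boundaries and lifts each piece.
#' Fetching each SEQ/DUP_COPY segment from the reference, reverse
#' complementing INV segments, and substituting the recorded novel sequence
#' for INS_NOVEL segments reproduces the host substring exactly. Zero-width
#' DEL_GAP rows are included when a deletion join point falls strictly
#' inside the interval, so deletion-spanning reads pick up the DEL_GAP
#' region label.
#'
#' @param map Genome map tibble.
#' @param host_contig Host contig name.
#' @param start0,end0 0-based half-open host interval.
#' @return Tibble of segments in host order: `ref_contig`, `ref_start`
#'   (0-based, leftmost reference base of the segment), `len` (host bp;
#'   0 for DEL_GAP), `strand`, `feature`, `variant_id`, `host_start`.
#' @export
lift_interval <- function(map, host_contig, start0, end0) {
  blocks <- map[map$host_contig == host_contig, , drop = FALSE]
  if (nrow(blocks) == 0L) stop("unknown host contig ", host_contig, call. = FALSE)
  blocks <- blocks[order(blocks$host_start, -blocks$host_len), , drop = FALSE]
  cons <- consuming(blocks)
  clen <- cons$host_start[nrow(cons)] + cons$host_len[nrow(cons)]
  if (!(start0 >= 0L && start0 < end0 && end0 <= clen)) {
    stop("invalid host interval [", start0, ", ", end0, ") on ", host_contig,
         call. = FALSE)
  }
  out <- list()
  for (i in seq_len(nrow(blocks))) {
    b <- blocks[i, ]
    if (b$host_len == 0L) {  # DEL_GAP join point
      if (b$host_start > start0 && b$host_start < end0) {
        out[[length(out) + 1L]] <- tibble::tibble(
          ref_contig = b$ref_contig, ref_start = b$ref_start, len = 0L,
          strand = "+", feature = "DEL_GAP", variant_id = b$variant_id,
          host_start = b$host_start
        )
      }
      next
    }
    os <- max(start0, b$host_start)
    oe <- min(end0, b$host_start + b$host_len)
    if (os >= oe) next
    off_s <- os - b$host_start
    seg_len <- oe - os
    ref_start <- if (b$feature == "INV") {
      b$ref_start + b$host_len - (oe - b$host_start)
    } else if (b$feature == "INS_NOVEL") {
      b$ref_start  # breakpoint, independent of the offset into the insert
    } else {
      b$ref_start + off_s
    }
    out[[length(out) + 1L]] <- tibble::tibble(
      ref_contig = b$ref_contig, ref_start = as.integer(ref_start),
      len = as.integer(seg_len), strand = b$strand, feature = b$feature,
      variant_id = b$variant_id, host_start = os
    )
  }
  dplyr::arrange(dplyr::bind_rows(out), .data$host_start)
}

#' Check genome map well-formedness
#'
#' Verifies the block invariants: features valid; SEQ/DUP_COPY strand `+`
#' and INV strand `-`; per-feature length constraints; blocks with host
#' width tile `[0, contig length)` exactly; SEQ reference intervals
#' strictly increasing and non-overlapping within each host contig.
#'
#' @param map Genome map tibble.
#' @param host_lengths Optional named vector of expected host contig
#'   lengths.
#' @return `map`, invisibly; errors on the first violation.
#' @export
validate_genome_map <- function(map, host_lengths = NULL) {
  stopifnot(all(map$feature %in% MAP_FEATURES))
  bad <- map$feature %in% c("SEQ", "DUP_COPY") & map$strand != "+"
  if (any(bad)) stop("SEQ/DUP_COPY blocks must be strand +", call. = FALSE)
  if (any(map$feature == "INV" & map$strand != "-")) {
    stop("INV blocks must be strand -", call. = FALSE)
  }
  with(map, {
    if (any(feature %in% c("SEQ", "INV", "DUP_COPY") &
            (host_len != ref_len | host_len <= 0L))) {
      stop("SEQ/INV/DUP_COPY blocks need host_len == ref_len > 0", call. = FALSE)
    }
    if (any(feature == "INS_NOVEL" & (ref_len != 0L | host_len <= 0L))) {
      stop("INS_NOVEL blocks need ref_len == 0 and host_len > 0", call. = FALSE)
    }
    if (any(feature == "DEL_GAP" & (host_len != 0L | ref_len <= 0L))) {
      stop("DEL_GAP blocks need host_len == 0 and ref_len > 0", call. = FALSE)
    }
  })
  for (ctg in unique(map$host_contig)) {
    b <- consuming(map[map$host_contig == ctg, , drop = FALSE])
    b <- b[order(b$host_start), , drop = FALSE]
    ends <- b$host_start + b$host_len
    if (b$host_start[1] != 0L || any(b$host_start[-1] != ends[-nrow(b)])) {
      stop("host blocks of ", ctg, " do not tile the contig", call. = FALSE)
    }
    if (!is.null(host_lengths) && ctg %in% names(host_lengths) &&
        ends[nrow(b)] != host_lengths[[ctg]]) {
      stop("host blocks of ", ctg, " do not cover the full contig length", call. = FALSE)
    }
    sq <- b[b$feature == "SEQ", , drop = FALSE]
    if (nrow(sq) > 1L) {
      re <- sq$ref_start + sq$ref_len
      if (any(sq$ref_start[-1] < re[-nrow(sq)])) {
        stop("SEQ reference intervals of ", ctg, " not strictly increasing", call. = FALSE)
      }
    }
  }
  invisible(map)
}

MAP_FORMAT_HEADER <- "#simval_map\tv1"

#' Write / read the genome map as TSV
#'
#' One block per line with a versioned format header; the on-disk columns
#' mirror the in-memory tibble exactly.
#'
#' @param map Genome map tibble.
#' @param path File path.
#' @return `write_genome_map()` returns `path` invisibly;
#'   `read_genome_map()` returns the map tibble.
#' @export
write_genome_map <- function(map, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(MAP_FORMAT_HEADER, con)
  utils::write.table(map, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = ".")
  invisible(path)
}

#' @rdname write_genome_map
#' @export
read_genome_map <- function(path) {
  first <- readLines(path, n = 1L)
  if (!identical(first, MAP_FORMAT_HEADER)) {
    stop("not a simval map file (missing format header)", call. = FALSE)
  }
  df <- utils::read.table(path, sep = "\t", header = TRUE, skip = 1L,
                          na.strings = ".", colClasses = c(
                            host_contig = "character", host_start = "integer",
                            host_len = "integer", ref_contig = "character",
                            ref_start = "integer", ref_len = "integer",
                            strand = "character", feature = "character",
                            variant_id = "character"
                          ))
  tibble::as_tibble(df)
}
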