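# Paired-end read simulation from the perturbed diploid genome.
#
# Generation is organized in fixed-size chunks of read pairs; each chunk's
# RNG is seeded from (seed, chunk index), so splitting the chunks across
# shards never changes the output: shard FASTQs concatenated in shard order
# are byte-identical to a single-shard run.

READ_CHUNK <- 512L
BASES <- c("A", "C", "G", "T")

#' Read simulation parameters
#'
#' @param coverage Mean sequencing depth over the diploid genome (x).
#' @param read_len Read length in bp.
#' @param frag_mean,frag_sd Fragment length Normal parameters (bp); drawn
#'   lengths are clamped to `[read_len, 2 * frag_mean]` (and to the contig
#'   length).
#' @param sub_error_rate Per-base substitution error probability; errors
#'   never change a base to itself. Base qualities are constant at
#'   `round(-10 * log10(max(rate, 1e-4)))`.
#' @param seed Master RNG seed.
#' @param shards Number of shards the chunk stream is split into.
#' @return A `read_sim_params` list.
#' @export
read_sim_params <- function(coverage = 50, read_len = 100L, frag_mean = 400L,
                            frag_sd = 60L, sub_error_rate = 0.001,
                            seed = 1L, shards = 1L) {
  stopifnot(coverage > 0, read_len >= 1L, frag_mean >= read_len,
            sub_error_rate >= 0, sub_error_rate < 1, shards >= 1L)
  structure(
    list(coverage = coverage, read_len = as.integer(read_len),
         frag_mean = as.integer(frag_mean), frag_sd = frag_sd,
         sub_error_rate = sub_error_rate, seed = as.integer(seed),
         shards = as.integer(shards)),
    class = "read_sim_params"
  )
}

base_quality_char <- function(rate) {
  q <- round(-10 * log10(max(rate, 1e-4)))
  rawToChar(as.raw(min(q, 60) + 33L))
}

apply_sub_errors <- function(seqs, rate) {
  if (rate <= 0 || length(seqs) == 0L) return(seqs)
  L <- nchar(seqs[1])
  u <- matrix(stats::runif(length(seqs) * L), nrow = length(seqs))
  hits <- which(u < rate, arr.ind = TRUE)
  if (nrow(hits) > 0L) hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
  for (k in seq_len(nrow(hits))) {
    i <- hits[k, 1]; j <- hits[k, 2]
    orig <- substr(seqs[i], j, j)
    substr(seqs[i], j, j) <- sample(setdiff(BASES, orig), 1L)
  }
  seqs
}

# ---- fast per-contig lift index ------------------------------------------

blocks_index <- function(map) {
  lapply(split(map, map$host_contig), function(b) {
    b <- b[order(b$host_start, -b$host_len), , drop = FALSE]
    cons <- which(b$host_len > 0L)
    list(host_start = b$host_start, host_len = b$host_len,
         ref_contig = b$ref_contig, ref_start = b$ref_start,
         ref_len = b$ref_len, strand = b$strand, feature = b$feature,
         variant_id = b$variant_id,
         cons_pos = cons, cons_start = b$host_start[cons],
         clen = sum(b$host_len))
  })
}

# segments of host interval [s, e) against one contig's index; returns a
# plain list of parallel vectors in host order
lift_segments <- function(bl, s, e) {
  first_c <- findInterval(s, bl$cons_start)
  last_c <- findInterval(e - 1L, bl$cons_start)
  lo <- bl$cons_pos[first_c]
  hi <- if (last_c < length(bl$cons_pos)) bl$cons_pos[last_c + 1L] - 1L else length(bl$host_start)
  idx <- seq(lo, hi)
  rc <- character(); rs <- integer(); ln <- integer()
  st <- character(); ft <- character(); vid <- character(); hs_out <- integer()
  for (i in idx) {
    hl <- bl$host_len[i]; hs <- bl$host_start[i]
    if (hl == 0L) {
      if (hs > s && hs < e) {
        rc <- c(rc, bl$ref_contig[i]); rs <- c(rs, bl$ref_start[i])
        ln <- c(ln, 0L); st <- c(st, "+"); ft <- c(ft, bl$feature[i])
        vid <- c(vid, bl$variant_id[i]); hs_out <- c(hs_out, hs)
      }
      next
    }
    os <- max(s, hs); oe <- min(e, hs + hl)
    if (os >= oe) next
    seg_rs <- if (bl$feature[i] == "INV") {
      bl$ref_start[i] + bl$host_len[i] - (oe - hs)
    } else if (bl$feature[i] == "INS_NOVEL") {
      bl$ref_start[i]  # novel bases all anchor at the insertion breakpoint
    } else {
      bl$ref_start[i] + (os - hs)
    }
    rc <- c(rc, bl$ref_contig[i]); rs <- c(rs, as.integer(seg_rs))
    ln <- c(ln, oe - os); st <- c(st, bl$strand[i]); ft <- c(ft, bl$feature[i])
    vid <- c(vid, bl$variant_id[i]); hs_out <- c(hs_out, os)
  }
  o <- order(hs_out)
  list(ref_contig = rc[o], ref_start = rs[o], len = ln[o], strand = st[o],
       feature = ft[o], variant_id = vid[o], host_start = hs_out[o])
}

#' Enumerate all true reference alignments of one read
#'
#' Lifts the read's host interval through the genome map and enumerates the
#' locations a correct aligner could report. When every lifted segment is
#' plain colinear sequence (SEQ/DUP_COPY, strand `+`, reference-adjacent) a
#' single full-length alternative is produced. Otherwise each lifted
#' segment yields one alternative -- the segment anchored at its own
#' reference start with the rest soft-clipped -- so a read straddling, say,
#' an inversion edge is correct at either side. Bases inside a novel
#' insertion provide no reference anchor; a read entirely inside one gets a
#' single alternative at the insertion breakpoint labelled `INS_NOVEL`.
#'
#' @param map Genome map tibble (or a prebuilt index, internally).
#' @param host_contig Host contig name.
#' @param start0,end0 0-based half-open host interval of the read.
#' @return List with `alts` (parallel vectors `ref_contig`, `anchor0`,
#'   `strand`, `label`, `alen`, one entry per alternative) and `labels`
#'   (all region features the read touches).
#' @export
true_alignments <- function(map, host_contig, start0, end0) {
  bl <- if (is.data.frame(map)) blocks_index(map)[[host_contig]] else map[[host_contig]]
  if (is.null(bl)) stop("unknown host contig ", host_contig, call. = FALSE)
  seg <- lift_segments(bl, start0, end0)
  labels <- unique(seg$feature)
  live <- seg$len > 0L
  anchored <- live & seg$feature != "INS_NOVEL"
  if (!any(anchored)) {
    alts <- list(ref_contig = seg$ref_contig[which(live)[1]],
                 anchor0 = seg$ref_start[which(live)[1]],
                 strand = "+", label = "INS_NOVEL",
                 alen = sum(seg$len))
    return(list(alts = alts, labels = labels))
  }
  li <- which(live)
  colinear <- all(seg$feature[li] %in% c("SEQ", "DUP_COPY")) &&
    length(unique(seg$ref_contig[li])) == 1L &&
    all(seg$strand[li] == "+") &&
    !any(seg$len == 0L) &&
    all(seg$ref_start[li][-1] == (seg$ref_start[li] + seg$len[li])[-length(li)])
  if (colinear) {
    alts <- list(
      ref_contig = seg$ref_contig[li[1]], anchor0 = seg$ref_start[li[1]],
      strand = "+",
      label = if (any(seg$feature[li] == "DUP_COPY")) "DUP_COPY" else "SEQ",
      alen = sum(seg$len[li])
    )
  } else {
    ai <- which(anchored)
    alts <- list(ref_contig = seg$ref_contig[ai],
                 anchor0 = seg$ref_start[ai],
                 strand = seg$strand[ai], label = seg$feature[ai],
                 alen = seg$len[ai])
  }
  list(alts = alts, labels = labels)
}

# ---- truth encoding in read names ----------------------------------------

b64url_enc <- function(x) {
  gsub("=", "", chartr("+/", "-_", gsub("\n", "", jsonlite::base64_enc(charToRaw(x)))))
}

b64url_dec <- function(x) {
  pad <- (4L - nchar(x) %% 4L) %% 4L
  rawToChar(jsonlite::base64_dec(paste0(chartr("-_", "+/", x), strrep("=", pad))))
}

MAX_NAME_LEN <- 254L

fmt_alts <- function(alts) {
  paste(alts$ref_contig, alts$anchor0, alts$strand, alts$label, alts$alen,
        sep = ",", collapse = ";")
}

parse_alts <- function(txt) {
  alt_f <- strsplit(strsplit(txt, ";", fixed = TRUE)[[1]], ",", fixed = TRUE)
  if (length(alt_f) == 0L || any(lengths(alt_f) != 5L)) {
    stop("corrupt truth payload", call. = FALSE)
  }
  m <- do.call(rbind, alt_f)
  a0 <- as.integer(m[, 2]); al <- as.integer(m[, 5])
  if (anyNA(a0) || anyNA(al)) stop("corrupt truth payload", call. = FALSE)
  list(ref_contig = m[, 1], anchor0 = a0, strand = m[, 3], label = m[, 4],
       alen = al)
}

truth_payload <- function(hap, mates) {
  paste(hap,
        paste(mates[[1]]$labels, collapse = ","), fmt_alts(mates[[1]]$alts),
        paste(mates[[2]]$labels, collapse = ","), fmt_alts(mates[[2]]$alts),
        sep = "|")
}

parse_payload <- function(txt) {
  parts <- strsplit(txt, "|", fixed = TRUE)[[1]]
  if (length(parts) != 5L) stop("corrupt truth payload", call. = FALSE)
  list(hap = parts[1],
       mates = list(
         list(labels = strsplit(parts[2], ",", fixed = TRUE)[[1]],
              alts = parse_alts(parts[3])),
         list(labels = strsplit(parts[4], ",", fixed = TRUE)[[1]],
              alts = parse_alts(parts[5]))
       ))
}

#' Encode / decode a read pair's truth record in its read name
#'
#' Both mates of a pair carry the same name (as paired-end aligners
#' require): `vs:<read_id>:<base64url payload>`, where the payload packs the
#' originating haplotype and, for each mate, its region labels and every
#' alternative true alignment. Mate identity is therefore recovered from
#' the payload during validation, never from FLAG bits. Names contain no
#' whitespace or `/` and stay within the 254-character SAM query-name
#' limit; a payload that would overflow is replaced by `*` and stored in a
#' sidecar table keyed by `read_id`.
#'
#' @param read_id Read pair identifier (no `:` allowed).
#' @param hap Originating host contig.
#' @param mates List of two per-mate records, each `list(labels, alts)`
#'   with `alts` as produced by [true_alignments()].
#' @return `encode_truth()`: list with `name` and `overflow` (the payload
#'   string when it did not fit, else `NA`).
#' @export
encode_truth <- function(read_id, hap, mates) {
  payload <- b64url_enc(truth_payload(hap, mates))
  name <- paste0("vs:", read_id, ":", payload)
  if (nchar(name) > MAX_NAME_LEN) {
    list(name = paste0("vs:", read_id, ":*"), overflow = payload)
  } else {
    list(name = name, overflow = NA_character_)
  }
}

#' @rdname encode_truth
#' @param name Read name to decode.
#' @param sidecar Optional sidecar tibble (`read_id`, `payload`) for
#'   overflow names.
#' @return `decode_truth()`: list with `read_id`, `hap`, `mates` (two
#'   `list(labels, alts)` records). Errors carry class
#'   `simval_not_simulated` when the name does not look like a simulated
#'   read, `simval_corrupt_payload` when it does but the payload cannot be
#'   decoded.
#' @export
decode_truth <- function(name, sidecar = NULL) {
  if (!startsWith(name, "vs:")) {
    rlang::abort(paste0("not a simulated read: ", name),
                 class = "simval_not_simulated")
  }
  parts <- strsplit(name, ":", fixed = TRUE)[[1]]
  if (length(parts) != 3L) {
    rlang::abort(paste0("corrupt read name: ", name),
                 class = "simval_corrupt_payload")
  }
  payload <- parts[3]
  if (payload == "*") {
    if (is.null(sidecar)) {
      rlang::abort("overflow name but no sidecar supplied",
                   class = "simval_corrupt_payload")
    }
    hit <- sidecar$payload[sidecar$read_id == parts[2]]
    if (length(hit) != 1L) {
      rlang::abort(paste0("read ", parts[2], " missing from sidecar"),
                   class = "simval_corrupt_payload")
    }
    payload <- hit
  }
  rec <- tryCatch(suppressWarnings(parse_payload(b64url_dec(payload))),
                  error = function(e) NULL)
  if (is.null(rec)) {
    rlang::abort(paste0("corrupt truth payload in ", name),
                 class = "simval_corrupt_payload")
  }
  c(list(read_id = parts[2]), rec)
}

# ---- the built-in engine --------------------------------------------------

# chunk boundaries over pair indices; shard assignment is contiguous
chunk_plan <- function(n_pairs, shards) {
  n_chunks <- max(1L, ceiling(n_pairs / READ_CHUNK))
  tibble::tibble(
    chunk = seq_len(n_chunks),
    lo = (seq_len(n_chunks) - 1L) * READ_CHUNK + 1L,
    hi = pmin(seq_len(n_chunks) * READ_CHUNK, n_pairs),
    shard = ceiling(seq_len(n_chunks) * shards / n_chunks)
  )
}

# generate raw reads (geometry + sequences, no truth) for one chunk
gen_chunk <- function(haplotypes, usable, params, chunk, lo, hi, prefix) {
  n <- hi - lo + 1L
  lens <- nchar(haplotypes[usable])
  local_seed(derive_seed(params$seed, 1000L + chunk), {
    ci <- sample.int(length(usable), n, replace = TRUE, prob = lens)
    clen <- lens[ci]
    fl <- as.integer(round(stats::rnorm(n, params$frag_mean, params$frag_sd)))
    fl <- pmax(params$read_len, pmin(fl, 2L * params$frag_mean, clen))
    start0 <- as.integer(floor(stats::runif(n) * (clen - fl + 1)))
    s1 <- start0; e1 <- start0 + params$read_len
    s2 <- start0 + fl - params$read_len; e2 <- start0 + fl
    ctg <- usable[ci]
    seq1 <- unname(substring(haplotypes[ctg], s1 + 1L, e1))
    seq2 <- unname(revcomp(substring(haplotypes[ctg], s2 + 1L, e2)))
    seq1 <- apply_sub_errors(seq1, params$sub_error_rate)
    seq2 <- apply_sub_errors(seq2, params$sub_error_rate)
    ids <- sprintf("%s%07d", prefix, seq(lo, hi))
    tibble::tibble(
      pair_id = rep(seq(lo, hi), 2L),
      read_id = rep(ids, 2L),
      mate = rep(c(1L, 2L), each = n),
      contig = rep(ctg, 2L),
      start0 = c(s1, s2), end0 = c(e1, e2),
      strand = rep(c("+", "-"), each = n),
      seq = c(seq1, seq2)
    )
  })
}

# built-in engine satisfying the external-simulator adapter contract:
# takes the perturbed haplotypes and parameters, returns reads with host
# coordinates (the per-read truth input)
builtin_read_engine <- function(haplotypes, params, shard = NULL, prefix = "r") {
  total_len <- sum(nchar(haplotypes))
  n_pairs <- round(params$coverage * total_len / (2 * params$read_len))
  usable <- names(haplotypes)[nchar(haplotypes) >= params$frag_mean]
  skipped <- setdiff(names(haplotypes), usable)
  if (length(skipped) > 0L) {
    warning("contigs shorter than frag_mean skipped: ",
            paste(skipped, collapse = ", "), call. = FALSE)
  }
  if (length(usable) == 0L) stop("no contig long enough for fragments", call. = FALSE)
  empty <- tibble::tibble(pair_id = integer(), read_id = character(),
                          mate = integer(), contig = character(),
                          start0 = integer(), end0 = integer(),
                          strand = character(), seq = character())
  if (n_pairs < 1L) return(empty)
  plan <- chunk_plan(n_pairs, params$shards)
  if (!is.null(shard)) plan <- plan[plan$shard == shard, , drop = FALSE]
  if (nrow(plan) == 0L) return(empty)  # more shards than chunks
  chunks <- purrr::pmap(plan[, c("chunk", "lo", "hi")], function(chunk, lo, hi) {
    gen_chunk(haplotypes, usable, params, chunk, lo, hi, prefix)
  })
  dplyr::arrange(dplyr::bind_rows(chunks), .data$pair_id, .data$mate)
}

#' Annotate engine reads with encoded ground truth
#'
#' Applies [true_alignments()] to every read's host interval and encodes
#' the per-pair result into the (shared) read name via [encode_truth()].
#' This is the second half of the adapter contract: any external engine
#' that returns reads with host coordinates can be routed through it
#' unchanged.
#'
#' @param reads Tibble from a read engine: `pair_id`, `read_id`, `mate`,
#'   `contig`, `start0`, `end0`, `strand`, `seq`.
#' @param map Genome map tibble.
#' @param params A [read_sim_params()] (for the quality string).
#' @return Reads tibble with `qual`, `name` (identical for both mates of a
#'   pair), `labels` (comma-joined, per mate), `n_alts` and an `alts`
#'   list-column; overflow payloads are in `attr(, "sidecar")`.
#' @export
annotate_truth <- function(reads, map, params) {
  idx <- blocks_index(map)
  n <- nrow(reads)
  if (any(is.na(reads$contig) | is.na(reads$start0) | is.na(reads$end0))) {
    bad <- reads$read_id[which(is.na(reads$contig) | is.na(reads$start0) | is.na(reads$end0))[1]]
    stop("engine returned no truth coordinates for read ", bad, call. = FALSE)
  }
  for (ctg in unique(reads$contig)) {
    bl <- idx[[ctg]]
    if (is.null(bl)) stop("engine read on unknown contig ", ctg, call. = FALSE)
    sel <- reads$contig == ctg
    if (any(reads$start0[sel] < 0L | reads$end0[sel] > bl$clen)) {
      bad <- reads$read_id[sel][which(reads$start0[sel] < 0L | reads$end0[sel] > bl$clen)[1]]
      stop("engine read ", bad, " outside host contig range", call. = FALSE)
    }
  }
  qual <- strrep(base_quality_char(params$sub_error_rate), params$read_len)
  alts <- vector("list", n)
  labels <- character(n); n_alts <- integer(n)
  for (i in seq_len(n)) {
    tr <- true_alignments(idx, reads$contig[i], reads$start0[i], reads$end0[i])
    alts[[i]] <- tr$alts
    labels[i] <- paste(tr$labels, collapse = ",")
    n_alts[i] <- length(tr$alts$anchor0)
  }
  # one shared name per pair, packing both mates
  ord1 <- which(reads$mate == 1L)
  names_out <- character(n)
  over <- list()
  m2_lookup <- stats::setNames(seq_len(n), paste(reads$pair_id, reads$mate))
  for (i in ord1) {
    j <- unname(m2_lookup[paste(reads$pair_id[i], 2L)])
    if (is.na(j)) stop("mate 2 missing for pair ", reads$read_id[i], call. = FALSE)
    mates <- list(
      list(labels = strsplit(labels[i], ",", fixed = TRUE)[[1]], alts = alts[[i]]),
      list(labels = strsplit(labels[j], ",", fixed = TRUE)[[1]], alts = alts[[j]])
    )
    enc <- encode_truth(reads$read_id[i], reads$contig[i], mates)
    names_out[i] <- enc$name
    names_out[j] <- enc$name
    if (!is.na(enc$overflow)) {
      over[[length(over) + 1L]] <- tibble::tibble(read_id = reads$read_id[i],
                                                  payload = enc$overflow)
    }
  }
  out <- reads
  out$qual <- qual
  out$name <- names_out
  out$labels <- labels
  out$n_alts <- n_alts
  out$alts <- alts
  attr(out, "sidecar") <- dplyr::bind_rows(over)
  out
}

#' Simulate paired-end reads with encoded truth
#'
#' Runs the built-in engine (uniform fragment placement weighted by contig
#' length, Normal fragment sizes, substitution-only errors with flat
#' qualities) and annotates every read with its true reference alignments.
#' The number of pairs is `round(coverage * total_length / (2 * read_len))`.
#' Mate 1 reads the fragment's left end on the forward strand; mate 2 reads
#' the right end reverse-complemented. Fully deterministic given
#' `params$seed`, independent of `shards`.
#'
#' @param haplotypes Named character vector of host contigs (from
#'   [build_diploid()]).
#' @param map Genome map tibble.
#' @param params A [read_sim_params()].
#' @param shard If given, generate only that shard's contiguous slice of
#'   the chunk stream.
#' @param prefix Read-id prefix (no `:`).
#' @return Annotated reads tibble (see [annotate_truth()]).
#' @export
simulate_reads <- function(haplotypes, map, params = read_sim_params(),
                           shard = NULL, prefix = "r") {
  reads <- builtin_read_engine(haplotypes, params, shard = shard, prefix = prefix)
  annotate_truth(reads, map, params)
}

#' Route an external read engine through the adapter contract
#'
#' An engine is any function `engine(haplotypes, params, shard, prefix)`
#' returning a reads tibble with host coordinates (the contract of
#' [builtin_read_engine]); the package then computes and encodes truth
#' exactly as for the built-in engine. Engines returning reads out of host
#' range, on unknown contigs, or with missing coordinates are rejected.
#'
#' @param engine Engine function.
#' @inheritParams simulate_reads
#' @return Annotated reads tibble.
#' @export
simulate_with_engine <- function(engine, haplotypes, map,
                                 params = read_sim_params(), shard = NULL,
                                 prefix = "r") {
  reads <- engine(haplotypes, params, shard = shard, prefix = prefix)
  annotate_truth(reads, map, params)
}

#' Write reads to paired FASTQ files
#'
#' Emits `<prefix>_1.fq` / `<prefix>_2.fq`; both mates of a pair share one
#' name (mate identity lives in the name payload, not in a `/1` suffix) so
#' the files feed directly into paired-end aligners. `<prefix>_truth.tsv`
#' is added when any name overflowed into the sidecar.
#'
#' @param reads Annotated reads tibble.
#' @param prefix Output path prefix.
#' @return Named character vector of the files written, invisibly.
#' @export
write_fastq <- function(reads, prefix) {
  out <- c(r1 = paste0(prefix, "_1.fq"), r2 = paste0(prefix, "_2.fq"))
  for (m in 1:2) {
    r <- reads[reads$mate == m, , drop = FALSE]
    r <- r[order(r$pair_id), , drop = FALSE]
    lines <- if (nrow(r) == 0L) character() else {
      as.vector(rbind(paste0("@", r$name), r$seq, "+", r$qual))
    }
    writeLines(lines, out[[m]])
  }
  sidecar <- attr(reads, "sidecar")
  if (!is.null(sidecar) && nrow(sidecar) > 0L) {
    sc <- paste0(prefix, "_truth.tsv")
    utils::write.table(sidecar, sc, sep = "\t", quote = FALSE, row.names = FALSE)
    out <- c(out, sidecar = sc)
  }
  invisible(out)
}

#' Read a truth sidecar table
#'
#' @param path Sidecar TSV path.
#' @return Tibble with `read_id`, `payload`.
#' @export
read_truth_sidecar <- function(path) {
  tibble::as_tibble(utils::read.table(path, sep = "\t", header = TRUE,
                                      colClasses = c("character", "character")))
}
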