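# Independent oracles and tiny fixture builders shared by the test files.
# The oracles are deliberately naive (string surgery, exhaustive search) so
# they stay independent of the package's block-map and matcher code paths.

# quick constructor for a single-row variant tibble
toy_variant <- function(chrom, pos, ref, alt, var_type, svlen,
                        ins_seq = NA_character_, dup_copies = NA_integer_,
                        gt1 = 1L, gt2 = 1L, id = "v1") {
  tibble::tibble(chrom = chrom, pos = as.integer(pos), id = id, ref = ref,
                 alt = alt, var_type = var_type, svlen = as.integer(svlen),
                 ins_seq = ins_seq, dup_copies = as.integer(dup_copies),
                 gt1 = as.integer(gt1), gt2 = as.integer(gt2))
}

revcomp_naive <- function(x) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = "")
}

# apply variants to a sequence by direct string surgery, right-to-left so
# earlier coordinates stay valid
apply_variants_naive <- function(ref_seq, variants) {
  v <- variants[order(variants$pos, decreasing = TRUE), , drop = FALSE]
  s <- ref_seq
  for (i in seq_len(nrow(v))) {
    p <- v$pos[i]
    switch(v$var_type[i],
      SNV = , MNP = {
        substr(s, p, p + nchar(v$ref[i]) - 1L) <- v$alt[i]
      },
      DEL = {
        w <- abs(v$svlen[i])
        s <- paste0(substr(s, 1, p), substr(s, p + w + 1L, nchar(s)))
      },
      INS = {
        s <- paste0(substr(s, 1, p), v$ins_seq[i], substr(s, p + 1L, nchar(s)))
      },
      INV = {
        w <- v$svlen[i]
        s <- paste0(substr(s, 1, p), revcomp_naive(substr(s, p + 1L, p + w)),
                    substr(s, p + w + 1L, nchar(s)))
      },
      DUP = {
        w <- v$svlen[i]
        span <- substr(s, p + 1L, p + w)
        s <- paste0(substr(s, 1, p + w),
                    strrep(span, v$dup_copies[i] - 1L),
                    substr(s, p + w + 1L, nchar(s)))
      }
    )
  }
  s
}

# every VCF encoding (pos, ref, alt) of the same indel edit, found by brute
# force: slide a window over the neighbourhood and keep encodings whose
# naive application reproduces the canonical edited sequence
enumerate_equivalent_encodings <- function(ref_seq, v, window = 40L) {
  target <- apply_variants_naive(ref_seq, v)
  w <- abs(v$svlen[1])
  out <- list()
  for (p in seq(max(1L, v$pos[1] - window), min(nchar(ref_seq) - w, v$pos[1] + window))) {
    cand <- v
    cand$pos <- as.integer(p)
    if (v$var_type[1] == "DEL") {
      cand$ref <- substr(ref_seq, p, p + w)
      cand$alt <- substr(ref_seq, p, p)
    } else {
      # insertion of the unit that begins right after p in the edited string
      ins <- substr(target, p + 1L, p + w)
      cand$ref <- substr(ref_seq, p, p)
      cand$alt <- paste0(cand$ref, ins)
      cand$ins_seq <- ins
    }
    if (cand$ref == cand$alt) next
    if (substr(ref_seq, p, p) != substr(cand$ref, 1, 1)) next
    if (identical(apply_variants_naive(ref_seq, cand), target)) {
      out[[length(out) + 1L]] <- cand
    }
  }
  dplyr::bind_rows(out)
}

# exhaustive one-to-one SV matcher: enumerates every maximal matching over
# the candidate pairs and returns them as canonical strings
all_max_matchings <- function(pairs) {
  if (nrow(pairs) == 0L) return(list(character()))
  best <- list(); best_size <- -1L
  recurse <- function(remaining, chosen, used_t, used_c) {
    if (nrow(remaining) == 0L) {
      if (length(chosen) > best_size) {
        best_size <<- length(chosen); best <<- list(sort(chosen))
      } else if (length(chosen) == best_size) {
        key <- sort(chosen)
        if (!any(vapply(best, identical, logical(1), y = key))) {
          best[[length(best) + 1L]] <<- key
        }
      }
      return(invisible())
    }
    p <- remaining[1, ]
    rest <- remaining[-1, , drop = FALSE]
    if (!(p$ti %in% used_t) && !(p$ci %in% used_c)) {
      recurse(rest, c(chosen, paste0(p$ti, ":", p$ci)),
              c(used_t, p$ti), c(used_c, p$ci))
    }
    recurse(rest, chosen, used_t, used_c)
  }
  recurse(pairs, character(), integer(), integer())
  best
}

# candidate SV pairs under the package's published matching rule, computed
# independently here
sv_candidate_pairs <- function(truth, calls, params) {
  out <- list()
  for (ti in seq_len(nrow(truth))) {
    for (ci in seq_len(nrow(calls))) {
      if (truth$var_type[ti] != calls$var_type[ci]) next
      if (truth$chrom[ti] != calls$chrom[ci]) next
      d <- abs(truth$pos[ti] - calls$pos[ci])
      r <- min(abs(truth$svlen[ti]), abs(calls$svlen[ci])) /
        max(abs(truth$svlen[ti]), abs(calls$svlen[ci]))
      if (d <= params$bp_tolerance && r >= params$size_ratio_min) {
        out[[length(out) + 1L]] <- tibble::tibble(ti = ti, ci = ci)
      }
    }
  }
  dplyr::bind_rows(c(list(tibble::tibble(ti = integer(), ci = integer())), out))
}

# shared smoke pipeline, built once per test run
.smoke_cache <- new.env(parent = emptyenv())
get_smoke <- function(coverage = 5, err = 0, seed = 1) {
  key <- paste("smoke", coverage, err, seed, sep = "_")
  if (!exists(key, .smoke_cache)) {
    fx <- suppressWarnings(smoke_fixture(seed = seed))
    ref <- fx$reference$sequences
    db <- normalize_variants(fx$db, ref)
    spec <- sampling_spec(n_snv = 50, n_indel = 20, n_sv = 5, seed = seed)
    truth <- sample_truth(db, spec, ref, fx$pool)
    dip <- build_diploid(ref, truth)
    params <- read_sim_params(coverage = coverage, sub_error_rate = err,
                              seed = seed)
    reads <- simulate_reads(dip$haplotypes, dip$map, params)
    assign(key, list(fx = fx, ref = ref, db = db, spec = spec, truth = truth,
                     dip = dip, params = params, reads = reads), .smoke_cache)
  }
  get(key, .smoke_cache)
}

# reconstruct a host contig from the reference through the map (the
# liftover reconstruction property), using truth records for novel inserts
reconstruct_host <- function(dip, truth, ref, ctg) {
  # in-place substitutions (SNV/MNP) live inside SEQ blocks; re-fetching from
  # the reference must apply them from the truth set first
  hap <- sub("^.*_hap", "", ctg)
  base_ctg <- sub("_hap[AB]$", "", ctg)
  gt <- if (hap == "A") truth$gt1 else truth$gt2
  subs <- truth[gt == 1L & truth$chrom == base_ctg &
                  truth$var_type %in% c("SNV", "MNP"), , drop = FALSE]
  rseq <- ref[[base_ctg]]
  for (i in seq_len(nrow(subs))) {
    substr(rseq, subs$pos[i], subs$pos[i] + nchar(subs$ref[i]) - 1L) <- subs$alt[i]
  }
  ref <- stats::setNames(list(rseq), base_ctg)
  segs <- lift_interval(dip$map, ctg, 0L, nchar(dip$haplotypes[[ctg]]))
  ins_starts <- dip$map[dip$map$host_contig == ctg & dip$map$feature == "INS_NOVEL", ]
  pieces <- character(nrow(segs))
  for (i in seq_len(nrow(segs))) {
    s <- segs[i, ]
    if (s$len == 0L) { pieces[i] <- ""; next }
    if (s$feature == "INS_NOVEL") {
      full <- truth$ins_seq[truth$id == s$variant_id][1]
      off <- s$host_start - ins_starts$host_start[ins_starts$variant_id == s$variant_id][1]
      pieces[i] <- substr(full, off + 1L, off + s$len)
    } else {
      p <- substr(ref[[s$ref_contig]], s$ref_start + 1L, s$ref_start + s$len)
      pieces[i] <- if (s$strand == "-") revcomp_naive(p) else p
    }
  }
  paste(pieces, collapse = "")
}
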