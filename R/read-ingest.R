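#' Ingestion thresholds for single-molecule methylation calls
#'
#' @param min_map_qs Minimum mapping quality (default 10).
#' @param min_read_qs Minimum mean basecall quality of a read (default 9).
#' @param low,high Binarization cutpoints: methylation probability
#'   `<= low` is called unmethylated (0), `>= high` methylated (1), and the
#'   intermediate band is discarded. Defaults 0.2/0.8; `mode = "r10"`
#'   selects the wider 0.3/0.7 discard band used for R10-pore calls
#'   (inclusive bounds).
#' @param mode `"r9"` or `"r10"` preset for the binarization band.
#' @param max_features_per_read Reads covering more than this many model
#'   CpGs are excluded entirely (default 10).
#' @param noise_floor Minimum noise term (default 0.05).
#' @param base_count Base read count the likelihood is standardized to
#'   (default 300).
#' @param cfdna_length_range Inclusive read-length window used by
#'   [filter_cfdna_lengths()] (default `c(50, 700)`).
#' @param count_features `"retained"` (count model CpGs per read after the
#'   discard band is removed, default) or `"raw"` (before).
#' @return A list of class `ingest_config`.
#' @export
ingest_config <- function(min_map_qs = 10L, min_read_qs = 9,
                          low = NULL, high = NULL,
                          mode = c("r9", "r10"),
                          max_features_per_read = 10L, noise_floor = 0.05,
                          base_count = 300,
                          cfdna_length_range = c(50L, 700L),
                          count_features = c("retained", "raw")) {
  mode <- match.arg(mode)
  band <- if (mode == "r9") c(0.2, 0.8) else c(0.3, 0.7)
  low <- low %||% band[1]
  high <- high %||% band[2]
  if (low >= high) abort("`low` must be below `high`.")
  structure(
    list(min_map_qs = min_map_qs, min_read_qs = min_read_qs, low = low,
         high = high, mode = mode,
         max_features_per_read = max_features_per_read,
         noise_floor = noise_floor, base_count = base_count,
         cfdna_length_range = cfdna_length_range,
         count_features = match.arg(count_features)),
    class = "ingest_config"
  )
}

#' Read a probe manifest (BED-like)
#'
#' Four tab-separated columns without header: chromosome, 0-based start of
#' the CpG cytosine on the forward strand, end, probe ID.
#'
#' @param path Manifest file path.
#' @return Tibble with columns `chrom`, `start`, `end`, `probe_id`.
#' @export
read_manifest <- function(path) {
  tb <- readr::read_tsv(path, col_names = c("chrom", "start", "end",
                                            "probe_id"),
                        col_types = "ciic", progress = FALSE)
  if (nrow(tb) == 0L || anyNA(tb$start) || anyNA(tb$probe_id)) {
    abort("Malformed probe manifest (expect chrom, start, end, probe_id).")
  }
  tb
}

# Decode SAM MM/ML base-modification tags for 5mC in CpG context on one
# read. `seq` is the alignment-orientation sequence; base-modification
# deltas index cytosines of the original (sequencing-orientation) read, so
# reverse-strand alignments are handled by counting on the reverse
# complement and mapping positions back. ML bytes are scaled by 1/255.
# Returns query (1-based, alignment orientation) positions and
# probabilities, or NULL when no C+m item is present.
decode_mm_ml <- function(mm, ml, seq, reverse) {
  if (is.null(mm) || is.na(mm) || !nzchar(mm) || is.null(ml)) return(NULL)
  items <- strsplit(sub(";$", "", mm), ";", fixed = TRUE)[[1]]
  specs <- regmatches(items, regexec("^([ACGTUN])([+-])([a-zA-Z0-9]+)\\??",
                                     items))
  offset <- 0L
  for (it in seq_along(items)) {
    sp <- specs[[it]]
    if (!length(sp)) next
    deltas <- suppressWarnings(
      as.integer(strsplit(items[it], ",", fixed = TRUE)[[1]][-1]))
    n_vals <- length(deltas) * nchar(sp[4])
    if (sp[2] == "C" && sp[3] == "+" && sp[4] == "m") {
      if (!length(deltas)) return(NULL)
      orig <- if (reverse) revcomp(seq) else seq
      c_pos <- which(strsplit(orig, "", fixed = TRUE)[[1]] == "C")
      ordinal <- cumsum(deltas + 1L)
      if (max(ordinal) > length(c_pos)) return(NULL) # malformed
      orig_pos <- c_pos[ordinal]
      qpos <- if (reverse) nchar(seq) - orig_pos + 1L else orig_pos
      probs <- ml[offset + seq_along(deltas)] / 255
      return(list(qpos = qpos, prob = probs))
    }
    offset <- offset + n_vals
  }
  NULL
}

revcomp <- function(x) {
  chartr("ACGTacgt", "TGCAtgca", paste(rev(strsplit(x, "", fixed = TRUE)[[1]]),
                                       collapse = ""))
}

# Map 1-based query positions to 1-based reference positions through the
# CIGAR (aligned blocks only; positions in insertions/clips return NA).
query_to_ref <- function(qpos, cigar, pos) {
  ops <- c("M", "=", "X")
  qr <- GenomicAlignments::cigarRangesAlongQuerySpace(cigar, ops = ops)[[1]]
  rr <- GenomicAlignments::cigarRangesAlongReferenceSpace(cigar, ops = ops,
                                                          pos = pos)[[1]]
  out <- rep(NA_integer_, length(qpos))
  qs <- IRanges::start(qr); qe <- IRanges::end(qr); rs <- IRanges::start(rr)
  for (b in seq_along(qs)) {
    hit <- qpos >= qs[b] & qpos <= qe[b]
    out[hit] <- rs[b] + (qpos[hit] - qs[b])
  }
  out
}

#' Extract methylation calls from an aligned, modification-tagged BAM
#'
#' Streams primary alignments with mapping quality at or above the
#' configured minimum, decodes per-read CpG methylation probabilities from
#' the MM/ML tags, and intersects them with the probe manifest. Calls on
#' the reverse strand are collapsed onto the forward-strand probe position
#' (CpG methylation is strand-symmetric). If a read yields several calls at
#' one probe, the first in file order is kept.
#'
#' @param bam_file Path to a BAM with MM/ML tags.
#' @param manifest Manifest tibble from [read_manifest()] (or a path).
#' @param config An [ingest_config()].
#' @return Calls tibble with the columns `epic_id`, `methylation`,
#'   `scores_per_read`, `binary_methylation` (NA until [binarize_calls()]),
#'   `read_id`, `start_time`, `run_id`, `QS`, `read_length`, `map_qs`,
#'   sorted by `start_time`. Attribute `counters` records reads seen,
#'   kept and skipped (and why).
#' @export
extract_calls <- function(bam_file, manifest, config = ingest_config()) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq", "qual"),
    tag = c("MM", "ML", "Mm", "Ml", "st", "RG"))
  b <- Rsamtools::scanBam(bam_file, param = param)[[1]]
  n <- length(b$qname)
  tag_of <- function(name, i) {
    v <- b$tag[[name]]
    if (is.null(v) || length(v) < i) return(NULL)
    x <- v[[i]]
    if (length(x) == 0L || (length(x) == 1L && is.na(x))) NULL else x
  }
  counters <- c(seen = n, kept = 0L, not_primary = 0L, low_mapq = 0L,
                low_qs = 0L, no_tags = 0L, no_probe_overlap = 0L)
  rows <- vector("list", n)
  key <- paste(manifest$chrom, manifest$start)
  for (i in seq_len(n)) {
    flag <- b$flag[i]
    if (bitwAnd(flag, 0x4) || bitwAnd(flag, 0x100) || bitwAnd(flag, 0x800)) {
      counters["not_primary"] <- counters["not_primary"] + 1L
      next
    }
    if (is.na(b$mapq[i]) || b$mapq[i] < config$min_map_qs) {
      counters["low_mapq"] <- counters["low_mapq"] + 1L
      next
    }
    qual <- as.character(b$qual[i])
    qs <- mean(utf8ToInt(qual) - 33L)
    if (is.nan(qs)) qs <- 0
    if (qs < config$min_read_qs) {
      counters["low_qs"] <- counters["low_qs"] + 1L
      next
    }
    seq <- as.character(b$seq[i])
    reverse <- bitwAnd(flag, 0x10) > 0
    mm <- tag_of("MM", i) %||% tag_of("Mm", i)
    ml <- tag_of("ML", i) %||% tag_of("Ml", i)
    dec <- if (is.null(mm) || is.null(ml)) NULL else {
      decode_mm_ml(mm, as.integer(ml), seq, reverse)
    }
    if (is.null(dec)) {
      counters["no_tags"] <- counters["no_tags"] + 1L
      next
    }
    refpos <- query_to_ref(dec$qpos, b$cigar[i], b$pos[i])
    ok <- !is.na(refpos)
    # forward-strand C sits at the probe start; a reverse-strand call is at
    # the paired G, one base to the right of the probe's C
    probe_start <- (refpos[ok] - 1L) - if (reverse) 1L else 0L
    idx <- match(paste(as.character(b$rname[i]), probe_start), key)
    hit <- !is.na(idx)
    if (!any(hit)) {
      counters["no_probe_overlap"] <- counters["no_probe_overlap"] + 1L
      next
    }
    probes <- manifest$probe_id[idx[hit]]
    probs <- dec$prob[ok][hit]
    first <- !duplicated(probes)
    counters["kept"] <- counters["kept"] + 1L
    rows[[i]] <- tibble(
      epic_id = probes[first],
      methylation = probs[first],
      read_id = b$qname[i],
      start_time = as.numeric(tag_of("st", i) %||% 0),
      run_id = as.character(tag_of("RG", i) %||% "run"),
      QS = qs,
      read_length = nchar(seq),
      map_qs = as.integer(b$mapq[i])
    )
  }
  calls <- dplyr::bind_rows(rows)
  if (nrow(calls) == 0L) {
    calls <- tibble(epic_id = character(), methylation = numeric(),
                    read_id = character(), start_time = numeric(),
                    run_id = character(), QS = numeric(),
                    read_length = integer(), map_qs = integer())
  }
  calls <- calls |>
    dplyr::add_count(.data$read_id, name = "scores_per_read") |>
    dplyr::mutate(binary_methylation = NA_real_) |>
    dplyr::relocate("epic_id", "methylation", "scores_per_read",
                    "binary_methylation", "read_id", "start_time", "run_id",
                    "QS", "read_length", "map_qs") |>
    dplyr::arrange(.data$start_time, .data$read_id)
  attr(calls, "counters") <- counters
  calls
}

#' Binarize methylation probabilities
#'
#' Probabilities at or below `low` become unmethylated (0), at or above
#' `high` methylated (1); the intermediate band is discarded. Idempotent:
#' re-binarizing retained calls changes nothing.
#'
#' @param calls Calls tibble with a `methylation` column.
#' @param config An [ingest_config()] supplying the cutpoints.
#' @return The retained calls with `binary_methylation` filled in.
#' @export
binarize_calls <- function(calls, config = ingest_config()) {
  keep <- calls$methylation <= config$low | calls$methylation >= config$high
  out <- calls[keep, , drop = FALSE]
  out$binary_methylation <- as.numeric(out$methylation >= config$high)
  out
}

#' Per-call noise terms from methylation probabilities
#'
#' \eqn{\eta = \max(\mathrm{floor},\ 0.5 - |m - 0.5|)}: calls near 0.5 are
#' maximally uncertain, confident calls are floored at 0.05 so adjusted
#' centroids stay inside `[0.05, 0.95]`.
#'
#' @param m Methylation probabilities in `[0, 1]`.
#' @param floor Noise floor (default 0.05).
#' @return Numeric vector of noise terms.
#' @export
compute_noise <- function(m, floor = 0.05) {
  pmax(floor, 0.5 - abs(m - 0.5))
}

#' Filter dense reads and attach read weights
#'
#' Reads covering more than `max_features_per_read` model CpGs are removed
#' entirely (their calls are strongly correlated); every surviving call
#' gets the read weight \eqn{r = 1 / \mathrm{features\ on\ the\ read}} and
#' the noise term from its methylation probability. Feature counts are
#' taken after the discard band is removed (configurable to pre-discard
#' counting via `count_features = "raw"`, in which case the input's
#' `scores_per_read` is used).
#'
#' @param calls Binarized calls tibble.
#' @param config An [ingest_config()].
#' @return Calls tibble with `features_on_read`, `read_weight` and `eta`
#'   columns; errors if nothing survives.
#' @export
filter_and_weight_reads <- function(calls, config = ingest_config()) {
  if (nrow(calls) == 0L) abort("no usable reads")
  out <- calls |>
    dplyr::add_count(.data$read_id, name = ".n_retained") |>
    dplyr::mutate(features_on_read = if (config$count_features == "retained") {
      .data$.n_retained
    } else {
      .data$scores_per_read
    }) |>
    dplyr::filter(.data$features_on_read <= config$max_features_per_read) |>
    dplyr::mutate(read_weight = 1 / .data$features_on_read,
                  eta = compute_noise(.data$methylation,
                                      config$noise_floor)) |>
    dplyr::select(-".n_retained")
  if (nrow(out) == 0L) abort("no usable reads")
  out
}

#' Keep calls observed within a time window
#'
#' @param calls Calls tibble with `start_time` (seconds since run start).
#' @param t_max Window end in seconds (`Inf` keeps everything).
#' @return Filtered calls.
#' @export
filter_time_window <- function(calls, t_max) {
  dplyr::filter(calls, .data$start_time <= t_max)
}

#' Keep calls from cfDNA-sized fragments
#'
#' Retains calls whose read length falls inside the inclusive window
#' (default 50-700 nucleotides, the cell-free DNA fragment range used for
#' CSF liquid biopsies).
#'
#' @param calls Calls tibble with `read_length`.
#' @param range Inclusive length bounds.
#' @return Filtered calls.
#' @export
filter_cfdna_lengths <- function(calls, range = c(50L, 700L)) {
  dplyr::filter(calls, .data$read_length >= range[1],
                .data$read_length <= range[2])
}

#' Write a methylation call table as Feather
#'
#' Emits exactly the ten ingest columns, rows sorted by `start_time`.
#'
#' @param calls Calls tibble.
#' @param path Output path (Feather v2).
#' @return `path`, invisibly.
#' @export
write_calls_feather <- function(calls, path) {
  cols <- c("epic_id", "methylation", "scores_per_read",
            "binary_methylation", "read_id", "start_time", "run_id", "QS",
            "read_length", "map_qs")
  out <- dplyr::arrange(calls[, cols], .data$start_time)
  arrow::write_feather(out, path)
  invisible(path)
}
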