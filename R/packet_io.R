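#' Packet framing, serialization and reassembly
#'
#' The belt and oximeter stream fixed-size packets of raw samples to a
#' gateway, which forwards them as JSON to a server. These functions frame a
#' contiguous sample series into packets, write/read the JSON interchange
#' format, reassemble packets into a [Recording] with a per-sample quality
#' mask, and quantify packet loss.
#'
#' @name packet_io
NULL

PACKET_FIELDS <- c("device_id", "device_kind", "seq", "fs_hz",
                   "t_start_ms", "t_transfer_ms", "samples")

#' Construct a single packet batch
#'
#' @param device_id opaque device identifier.
#' @param device_kind `"belt"` or `"oximeter"`.
#' @param seq non-negative integer sequence number.
#' @param fs_hz sampling rate in Hz (50 for the belt, 100 for the oximeter).
#' @param t_start_ms epoch milliseconds of the first sample.
#' @param t_transfer_ms epoch milliseconds of transfer (>= `t_start_ms`).
#' @param samples numeric vector of raw samples.
#' @return An object of class `packet_batch`.
#' @export
packet_batch <- function(device_id, device_kind, seq, fs_hz,
                         t_start_ms, t_transfer_ms, samples) {
  device_kind <- match.arg(device_kind, c("belt", "oximeter"))
  if (seq < 0 || seq != floor(seq)) stop("'seq' must be a non-negative integer")
  if (fs_hz <= 0) stop("'fs_hz' must be positive")
  if (t_transfer_ms < t_start_ms) stop("'t_transfer_ms' must be >= 't_start_ms'")
  structure(list(device_id = as.character(device_id),
                 device_kind = device_kind,
                 seq = as.integer(seq),
                 fs_hz = as.numeric(fs_hz),
                 t_start_ms = as.numeric(t_start_ms),
                 t_transfer_ms = as.numeric(t_transfer_ms),
                 samples = as.numeric(samples)),
            class = "packet_batch")
}

#' Frame a sample series into fixed-size packets
#'
#' Splits `samples` into consecutive packets of exactly `packet_size` samples;
#' a trailing remainder shorter than one packet is dropped. Packet `k`
#' (0-based) starts at `t0_ms + k * packet_size * 1000 / fs_hz`.
#'
#' @param samples numeric vector of raw samples.
#' @param fs_hz sampling rate in Hz.
#' @param packet_size samples per packet (default 400 for the belt: 8 s at
#'   50 Hz, aligning packets with analysis windows; use 100 for the oximeter).
#' @param t0_ms epoch milliseconds of the first sample.
#' @param device_id,device_kind device identity stamped on every packet.
#' @param transfer_lag_ms transfer delay added to each packet's start time.
#' @return List of [packet_batch] objects with `seq` 0, 1, ...
#' @export
frame_packets <- function(samples, fs_hz, packet_size = 400L, t0_ms = 0,
                          device_id = "dev0",
                          device_kind = c("belt", "oximeter"),
                          transfer_lag_ms = 0) {
  device_kind <- match.arg(device_kind)
  if (packet_size < 1 || packet_size != floor(packet_size))
    stop("'packet_size' must be a positive integer")
  if (fs_hz <= 0) stop("'fs_hz' must be positive")
  n_pkt <- length(samples) %/% packet_size
  if (n_pkt == 0) return(list())
  lapply(seq_len(n_pkt) - 1L, function(k) {
    t_start <- t0_ms + k * packet_size * 1000 / fs_hz
    idx <- (k * packet_size + 1L):((k + 1L) * packet_size)
    packet_batch(device_id, device_kind, k, fs_hz,
                 t_start, t_start + transfer_lag_ms, samples[idx])
  })
}

#' Write packets to a JSON file
#'
#' One JSON object per packet, newline-delimited (NDJSON). The reader also
#' accepts a top-level JSON array.
#'
#' @param packets list of [packet_batch] objects.
#' @param destination output file path.
#' @return `destination`, invisibly.
#' @export
write_packets <- function(packets, destination) {
  lines <- vapply(packets, function(p) {
    jsonlite::toJSON(unclass(p), auto_unbox = TRUE, digits = NA)
  }, character(1))
  writeLines(lines, destination)
  invisible(destination)
}

#' Read packets from a JSON file
#'
#' Accepts newline-delimited JSON (one packet object per line) or a single
#' top-level JSON array of packet objects.
#'
#' @param source input file path.
#' @return List of [packet_batch] objects.
#' @export
read_packets <- function(source) {
  txt <- readLines(source, warn = FALSE)
  txt <- txt[nzchar(trimws(txt))]
  if (length(txt) == 0) return(list())
  first <- substr(trimws(txt[1]), 1, 1)
  raw <- if (first == "[") {
    jsonlite::fromJSON(paste(txt, collapse = "\n"), simplifyVector = FALSE)
  } else {
    lapply(txt, jsonlite::fromJSON, simplifyVector = FALSE)
  }
  lapply(seq_along(raw), function(i) {
    p <- raw[[i]]
    missing <- setdiff(PACKET_FIELDS, names(p))
    if (length(missing) > 0)
      stop(sprintf("packet %d: missing field(s) %s", i,
                   paste(missing, collapse = ", ")))
    packet_batch(p$device_id, p$device_kind, p$seq, p$fs_hz,
                 p$t_start_ms, p$t_transfer_ms,
                 unlist(p$samples, use.names = FALSE))
  })
}

#' Construct a Recording
#'
#' A contiguous single-device sample series with a per-sample quality flag.
#'
#' @param subject_id opaque subject identifier.
#' @param device_kind `"belt"` or `"oximeter"`.
#' @param fs_hz sampling rate in Hz.
#' @param t0_ms epoch milliseconds of the first sample.
#' @param samples numeric vector.
#' @param quality character vector in `{"ok","missing","repaired"}`, recycled
#'   from `"ok"` when omitted.
#' @return An object of class `bcg_recording`.
#' @export
recording <- function(subject_id, device_kind, fs_hz, t0_ms, samples,
                      quality = NULL) {
  if (is.null(quality)) quality <- rep("ok", length(samples))
  stopifnot(length(quality) == length(samples))
  if (!all(quality %in% c("ok", "missing", "repaired")))
    stop("quality flags must be ok/missing/repaired")
  structure(list(subject_id = as.character(subject_id),
                 device_kind = device_kind,
                 fs_hz = as.numeric(fs_hz),
                 t0_ms = as.numeric(t0_ms),
                 samples = as.numeric(samples),
                 quality = as.character(quality)),
            class = "bcg_recording")
}

#' @export
print.bcg_recording <- function(x, ...) {
  cat(sprintf("<bcg_recording> subject %s, %s @ %g Hz, %d samples (%.1f s)\n",
              x$subject_id, x$device_kind, x$fs_hz, length(x$samples),
              length(x$samples) / x$fs_hz))
  tab <- table(factor(x$quality, levels = c("ok", "missing", "repaired")))
  cat(sprintf("  quality: %d ok, %d missing, %d repaired\n",
              tab[["ok"]], tab[["missing"]], tab[["repaired"]]))
  invisible(x)
}

#' Reassemble packets into a Recording
#'
#' Orders packets by sequence number, fills gaps in the sequence with zeros
#' flagged `missing`, and keeps the first occurrence of duplicated sequence
#' numbers. Downstream stages must consult the quality mask, never the fill
#' value.
#'
#' @param packets list of [packet_batch] objects sharing device identity and
#'   geometry.
#' @param subject_id subject identifier stamped on the Recording.
#' @param fill value used for missing samples (default 0).
#' @return A [recording] whose `missing` spans correspond exactly to gaps in
#'   the received sequence numbers.
#' @export
assemble <- function(packets, subject_id = "unknown", fill = 0) {
  if (length(packets) == 0) stop("no packets to assemble")
  ids <- unique(vapply(packets, `[[`, character(1), "device_id"))
  kinds <- unique(vapply(packets, `[[`, character(1), "device_kind"))
  fss <- unique(vapply(packets, `[[`, numeric(1), "fs_hz"))
  lens <- unique(vapply(packets, function(p) length(p$samples), integer(1)))
  if (length(ids) > 1 || length(kinds) > 1 || length(fss) > 1 || length(lens) > 1)
    stop("conflicting device metadata: packets do not belong to one stream")
  seqs <- vapply(packets, `[[`, integer(1), "seq")
  keep <- !duplicated(seqs)
  packets <- packets[keep]
  seqs <- seqs[keep]
  ord <- order(seqs)
  packets <- packets[ord]
  seqs <- seqs[ord]
  psz <- lens[1]
  n_slots <- max(seqs) - min(seqs) + 1L
  samples <- rep(as.numeric(fill), n_slots * psz)
  quality <- rep("missing", n_slots * psz)
  for (i in seq_along(packets)) {
    slot <- seqs[i] - min(seqs)
    idx <- (slot * psz + 1L):((slot + 1L) * psz)
    samples[idx] <- packets[[i]]$samples
    quality[idx] <- "ok"
  }
  t0 <- min(vapply(packets, `[[`, numeric(1), "t_start_ms"))
  recording(subject_id, kinds[1], fss[1], t0, samples, quality)
}

#' Packet loss ratio
#'
#' Fraction of expected packets that were not correctly transferred from the
#' device to the gateway.
#'
#' @param expected number of packets the device emitted (> 0).
#' @param received number of packets that arrived (0 <= received <= expected).
#' @return `(expected - received) / expected`, in `[0, 1]`.
#' @export
packet_loss_ratio <- function(expected, received) {
  if (expected <= 0) stop("'expected' must be positive")
  if (received < 0 || received > expected)
    stop("'received' must lie in [0, expected]")
  (expected - received) / expected
}
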