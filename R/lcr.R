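# Ligase-cycling-reaction assembly planning: for every junction between
# consecutive parts of a circular construct, design a single-stranded
# bridging oligo whose two halves anneal to the junction-proximal ends of
# the two parts, each half sized to reach the target melting temperature.

#' Design a bridging oligo for one part junction
#'
#' The left half is the minimal-length terminal (3') subsequence of the
#' upstream part with Tm >= \code{target_tm}; the right half is the
#' minimal-length initial (5') subsequence of the downstream part with
#' Tm >= \code{target_tm}. The search grows each half from \code{min_len}
#' one nucleotide at a time (deterministic shortest-qualifying tie-break)
#' up to \code{max_len}. The stored \code{sequence} is the top-strand
#' junction context \code{left_half + right_half}; the synthesized oligo
#' (\code{order_sequence}) is its reverse complement, which has the same
#' duplex Tm.
#'
#' @param upstream,downstream [dna_part()] objects (or plain DNA strings).
#' @param target_tm Target melting temperature in degrees Celsius
#'   (default 70, the LCR annealing target).
#' @param min_len,max_len Half-length search bounds in nt (defaults 15/60).
#' @param Na,conc Tm conditions, see [tm_nn()].
#' @return Object of class \code{bridging_oligo}.
#' @export
design_bridge <- function(upstream, downstream, target_tm = 70,
                          min_len = 15L, max_len = 60L,
                          Na = 0.05, conc = 250e-9) {
  up_id <- if (inherits(upstream, "dna_part")) upstream$id else "upstream"
  dn_id <- if (inherits(downstream, "dna_part")) downstream$id else "downstream"
  up <- toupper(if (inherits(upstream, "dna_part")) upstream$sequence else upstream)
  dn <- toupper(if (inherits(downstream, "dna_part")) downstream$sequence else downstream)
  junction <- paste0(up_id, "|", dn_id)

  grow <- function(seq, side) {
    L <- nchar(seq)
    for (len in seq(min(min_len, L), min(max_len, L))) {
      half <- if (side == "left") substr(seq, L - len + 1L, L)
              else substr(seq, 1L, len)
      tm <- tm_nn(half, Na = Na, conc = conc)
      if (tm >= target_tm) return(list(seq = half, tm = tm))
    }
    stop("junction ", junction, ": ", side, " half cannot reach Tm ",
         target_tm, " within ", min(max_len, L), " nt")
  }

  left <- grow(up, "left")
  right <- grow(dn, "right")
  seq <- paste0(left$seq, right$seq)
  structure(
    list(junction = c(upstream = up_id, downstream = dn_id),
         sequence = seq, order_sequence = revcomp(seq),
         left_half = left$seq, right_half = right$seq,
         tm_left = left$tm, tm_right = right$tm,
         target_tm = target_tm, conditions = c(Na = Na, conc = conc),
         id = paste0("BO_", fnv1a32_hex(seq))),
    class = "bridging_oligo"
  )
}

#' @export
print.bridging_oligo <- function(x, ...) {
  cat(sprintf("<bridging_oligo> %s (%s -> %s): %d nt, Tm %.1f / %.1f degC\n",
              x$id, x$junction[["upstream"]], x$junction[["downstream"]],
              nchar(x$sequence), x$tm_left, x$tm_right))
  invisible(x)
}

#' Plan LCR assembly of one construct
#'
#' Designs one bridging oligo per junction between consecutive parts,
#' including the circular closure junction from the last part back to the
#' first, so a construct of k parts needs exactly k oligos.
#'
#' @param record A [plasmid_record()] with >= 2 part features.
#' @param ... Passed to [design_bridge()].
#' @return List of \code{bridging_oligo} objects, one per junction, in
#'   feature order.
#' @export
plan_assembly <- function(record, ...) {
  stopifnot(inherits(record, "plasmid_record"))
  k <- nrow(record$features)
  if (k < 2L) {
    stop("record '", record$id,
         "' has fewer than 2 parts: no junctions to bridge")
  }
  lapply(seq_len(k), function(i) {
    j <- if (i == k) 1L else i + 1L
    up <- dna_part(record$features$part[i], role = record$features$role[i],
                   sequence = feature_sequence(record, i))
    dn <- dna_part(record$features$part[j], role = record$features$role[j],
                   sequence = feature_sequence(record, j))
    design_bridge(up, dn, ...)
  })
}

#' Pool the bridging oligos of a construct library
#'
#' Identical junction contexts across constructs yield identical oligos;
#' the pool deduplicates them by sequence so each is synthesized once.
#'
#' @param plans Named list (by construct id) of [plan_assembly()] outputs.
#' @return List with \code{oligos} (unique \code{bridging_oligo}s) and
#'   \code{usage} (data.frame construct / oligo id mapping).
#' @export
pool_oligos <- function(plans) {
  oligos <- list()
  usage <- list()
  for (cid in names(plans)) {
    for (bo in plans[[cid]]) {
      if (is.null(oligos[[bo$id]])) oligos[[bo$id]] <- bo
      usage[[length(usage) + 1L]] <- data.frame(
        construct = cid, oligo = bo$id,
        upstream = bo$junction[["upstream"]],
        downstream = bo$junction[["downstream"]],
        stringsAsFactors = FALSE
      )
    }
  }
  list(oligos = oligos, usage = do.call(rbind, usage))
}

#' Oligo order sheet
#'
#' @param pool Output of [pool_oligos()].
#' @param scale Synthesis scale annotation (default "25nm").
#' @return data.frame with id, sequence (the strand to synthesize), length
#'   and scale — ready to write as CSV.
#' @export
oligo_order_sheet <- function(pool, scale = "25nm") {
  data.frame(
    id = vapply(pool$oligos, `[[`, character(1), "id"),
    sequence = vapply(pool$oligos, `[[`, character(1), "order_sequence"),
    length = vapply(pool$oligos, function(o) nchar(o$sequence), integer(1)),
    scale = scale,
    row.names = NULL, stringsAsFactors = FALSE
  )
}
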