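# Synthetic-data generation: random DNA parts with controlled GC content
# and log-normal titer tables whose log10-scale means are a linear function
# of the design factors — the statistical structure the Learn stage
# assumes — so the full DBTL loop runs without laboratory data.

#' Generate random DNA parts
#'
#' Sequences are reproducible given the seed and have exact base
#' composition: the number of G+C bases is \code{round(gc * length)}
#' (split as evenly as possible between G and C, likewise A/T), with base
#' order a seeded random permutation, so observed GC is always within the
#' rounding error of the request.
#'
#' @param ids Character vector of part ids.
#' @param lengths Integer lengths (recycled), each >= 40 nt so bridging-
#'   oligo halves can exist on both sides of a junction.
#' @param gc Target GC fraction in [0, 1] (default 0.5).
#' @param seed Integer seed (mandatory).
#' @param roles Part roles (recycled; default \code{"gene"}).
#' @param lcr_ready If TRUE, sample each part conditional on both of its
#'   terminal windows being able to reach \code{target_tm} within
#'   \code{max_len} nt (rejection sampling, still deterministic per seed),
#'   so every junction between such parts admits a bridging oligo. Needs a
#'   GC content high enough for the target to be reachable at all.
#' @param target_tm,max_len LCR-readiness condition (defaults 70 degC /
#'   60 nt, the bridging-oligo defaults).
#' @return A [part_registry()].
#' @examples
#' random_parts(c("A", "B"), lengths = 100, seed = 1)
#' @export
random_parts <- function(ids, lengths, gc = 0.5, seed, roles = "gene",
                         lcr_ready = FALSE, target_tm = 70, max_len = 60L) {
  if (missing(seed)) stop("'seed' is mandatory for reproducible parts")
  if (!is.numeric(gc) || gc < 0 || gc > 1) stop("'gc' must be in [0, 1]")
  lengths <- rep_len(as.integer(lengths), length(ids))
  roles <- rep_len(roles, length(ids))
  if (any(lengths < 40L)) {
    stop("part lengths must be >= 40 nt (bridging halves must fit)")
  }
  end_ok <- function(s) {
    L <- nchar(s)
    reach <- function(sub) any(vapply(15:min(max_len, L), function(k) {
      tm_nn(substr(sub, 1L, k)) >= target_tm
    }, logical(1)))
    reach(s) && reach(revcomp(s)) # prefix, and suffix via the complement
  }
  with_seed(seed, {
    parts <- lapply(seq_along(ids), function(i) {
      L <- lengths[i]
      n_gc <- round(gc * L)
      n_at <- L - n_gc
      bases <- c(rep("G", ceiling(n_gc / 2)), rep("C", floor(n_gc / 2)),
                 rep("A", ceiling(n_at / 2)), rep("T", floor(n_at / 2)))
      for (try in seq_len(if (lcr_ready) 1000L else 1L)) {
        s <- paste(sample(bases), collapse = "")
        if (!lcr_ready || end_ok(s)) {
          return(dna_part(ids[i], role = roles[i], sequence = s))
        }
      }
      stop("part '", ids[i], "': no sequence at GC ", gc,
           " has ends reaching Tm ", target_tm, " within ", max_len,
           " nt; raise 'gc' or relax the target")
    })
    part_registry(parts)
  })
}

#' Observed GC fraction of a sequence
#'
#' @param x DNA string.
#' @return Fraction of G+C bases.
#' @export
gc_content <- function(x) {
  x <- toupper(x)
  n <- nchar(x)
  (n - nchar(gsub("[GC]", "", x))) / n
}

#' Define the ground truth of a titer simulation
#'
#' The response model is log-linear: per replicate,
#' \code{titer = 10^(baseline + sum(level effects) + Normal(0, sd))} —
#' log-normal noise, so titers are positive and can span orders of
#' magnitude, matching the main-effects structure [fit_effects()] models.
#'
#' @param effects Named list: analysis factor -> named numeric vector of
#'   per-level effects on log10 titer (ordinal factors keyed by rank as a
#'   string, e.g. \code{c("1" = -0.5, "2" = 0.5)}). Factors absent from
#'   the list contribute zero.
#' @param baseline Baseline log10 titer (mg/L scale).
#' @param sd Log10-scale noise standard deviation (>= 0).
#' @param n_replicates Replicates per construct (>= 1).
#' @param seed Integer seed (mandatory).
#' @return Object of class \code{ground_truth}.
#' @export
ground_truth <- function(effects = list(), baseline = -1.5, sd = 0.3,
                         n_replicates = 3, seed) {
  if (missing(seed)) stop("'seed' is mandatory")
  if (!is.numeric(sd) || sd < 0) stop("'sd' must be >= 0")
  if (n_replicates < 1) stop("'n_replicates' must be >= 1")
  stopifnot(is.list(effects))
  structure(
    list(effects = effects, baseline = baseline, sd = sd,
         n_replicates = as.integer(n_replicates), seed = as.integer(seed)),
    class = "ground_truth"
  )
}

#' Simulate a titer measurement table
#'
#' @param design Analysis design table ([gene_design()] or [slot_design()]
#'   output): one row per construct.
#' @param truth A [ground_truth()]. Every factor named in
#'   \code{truth$effects} must be a design column, and every design level
#'   encountered must have an effect entry.
#' @param intermediate Optional list \code{(gene=, mean=, sd=)} adding an
#'   \code{intermediate} column (log-normal relative peak area of an
#'   upstream pathway intermediate, e.g. cinnamic acid) to every row.
#' @return data.frame with columns \code{construct}, \code{replicate},
#'   \code{titer} (and \code{intermediate} if requested); deterministic
#'   given \code{truth$seed}.
#' @export
simulate_titers <- function(design, truth, intermediate = NULL) {
  stopifnot(is.data.frame(design), inherits(truth, "ground_truth"))
  unknown <- setdiff(names(truth$effects), names(design))
  if (length(unknown)) {
    stop("truth defines effects for factor(s) absent from the design: ",
         paste(unknown, collapse = ", "))
  }
  lp <- rep(truth$baseline, nrow(design))
  for (f in names(truth$effects)) {
    eff <- truth$effects[[f]]
    key <- as.character(design[[f]])
    missing_lv <- setdiff(unique(key), names(eff))
    if (length(missing_lv)) {
      stop("truth effect for factor '", f, "' misses level(s): ",
           paste(missing_lv, collapse = ", "))
    }
    lp <- lp + unname(eff[key])
  }
  n_rep <- truth$n_replicates
  with_seed(truth$seed, {
    out <- do.call(rbind, lapply(seq_len(nrow(design)), function(i) {
      noise <- stats::rnorm(n_rep, 0, truth$sd)
      data.frame(construct = design$construct[i],
                 replicate = seq_len(n_rep),
                 titer = 10^(lp[i] + noise),
                 stringsAsFactors = FALSE)
    }))
    if (!is.null(intermediate)) {
      out$intermediate <- 10^(intermediate$mean +
                                stats::rnorm(nrow(out), 0, intermediate$sd %||% 0))
    }
    out
  })
}
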