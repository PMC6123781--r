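# Robotics worklist generation for automated LCR assembly: part dilution,
# bridging-oligo pooling and LCR setup, as vendor-neutral CSV tables, plus
# a seeded random injection sequence for downstream analytics.

#' 96-well plate well names
#'
#' @param n How many wells (<= 96), row-major A1, A2, ... H12.
#' @return Character vector of well names.
#' @export
wells_96 <- function(n = 96) {
  if (n > 96) stop("a 96-well plate has 96 wells")
  all <- as.vector(t(outer(LETTERS[1:8], 1:12, paste0)))
  all[seq_len(n)]
}

#' Assign source-plate wells to parts and oligos
#'
#' Deterministic layout: unique parts fill a parts plate A1.., unique
#' oligos fill oligo plates A1.. (spilling to further plates past 96).
#' Each labware gets a pseudo-barcode derived from its name.
#'
#' @param plans Named list (by construct id) of [plan_assembly()] outputs.
#' @param registry Optional [part_registry()] restricting/ordering parts.
#' @return Layout list with \code{parts} and \code{oligos} lookup tables
#'   (data.frames: id, labware, well, barcode).
#' @export
auto_layout <- function(plans, registry = NULL) {
  pool <- pool_oligos(plans)
  part_ids <- unique(unlist(lapply(plans, function(pl) {
    vapply(pl, function(bo) bo$junction, character(2))
  })))
  if (!is.null(registry)) part_ids <- intersect(names(registry), part_ids)

  place <- function(ids, prefix) {
    n <- length(ids)
    plate_idx <- (seq_len(n) - 1L) %/% 96L + 1L
    well_idx <- (seq_len(n) - 1L) %% 96L + 1L
    labware <- paste0(prefix, "_", plate_idx)
    data.frame(id = ids, labware = labware,
               well = vapply(well_idx, function(i) wells_96(96)[i], character(1)),
               barcode = paste0("BC", toupper(substr(vapply(labware, fnv1a32_hex,
                                                            character(1)), 1, 6))),
               row.names = NULL, stringsAsFactors = FALSE)
  }
  list(parts = place(part_ids, "parts_plate"),
       oligos = place(vapply(pool$oligos, `[[`, character(1), "id"),
                      "oligo_plate"))
}

#' @noRd
lookup_well <- function(layout_df, ids, what) {
  idx <- match(ids, layout_df$id)
  if (anyNA(idx)) {
    stop("no source well mapped for ", what, ": ",
         paste(unique(ids[is.na(idx)]), collapse = ", "))
  }
  layout_df[idx, , drop = FALSE]
}

#' Generate LCR robotics worklists for a construct library
#'
#' Emits the three liquid-handling stages of automated LCR assembly:
#' \enumerate{
#'   \item \code{part_dilution} — each unique part is diluted with water
#'     from its stock concentration to the working concentration
#'     (default 750 -> 75 nM) on a dilution plate;
#'   \item \code{oligo_pooling} — each construct's bridging oligos are
#'     pooled into one well per construct;
#'   \item \code{lcr_setup} — each construct's destination well receives
#'     its diluted parts, its oligo pool and a water fill up to the
#'     reaction volume, so per-destination volumes always sum exactly to
#'     \code{reaction_volume}.
#' }
#' A randomized \code{injection_sequence} (instrument sample order for
#' downstream analysis) is drawn from the explicit seed; the same seed
#' reproduces byte-identical worklists.
#'
#' @param plans Named list (by construct id) of [plan_assembly()] outputs.
#' @param layout Source layout from [auto_layout()] (default: computed).
#' @param seed Integer seed for the injection-sequence permutation.
#' @param reaction_volume LCR reaction volume in uL (default 25).
#' @param part_volume uL of each diluted part per reaction (default 2).
#' @param oligo_pool_volume uL of pooled oligos per reaction (default 5).
#' @param oligo_volume uL of each oligo into its construct pool (default 2).
#' @param stock_nM,target_nM Part stock and working concentrations
#'   (defaults 750 and 75 nM); sets the dilution ratio.
#' @param dilution_volume Final volume of each part dilution, uL.
#' @param well_capacity Maximum volume a destination well holds, uL.
#' @return Object of class \code{lcr_worklists}: data.frames
#'   \code{part_dilution}, \code{oligo_pooling}, \code{lcr_setup},
#'   \code{injection_sequence}.
#' @export
generate_worklists <- function(plans, layout = NULL, seed = 1L,
                               reaction_volume = 25, part_volume = 2,
                               oligo_pool_volume = 5, oligo_volume = 2,
                               stock_nM = 750, target_nM = 75,
                               dilution_volume = 100,
                               well_capacity = 200) {
  empty_wl <- function() {
    data.frame(source_labware = character(0), source_barcode = character(0),
               source_well = character(0), dest_labware = character(0),
               dest_barcode = character(0), dest_well = character(0),
               volume = numeric(0), reagent = character(0),
               stringsAsFactors = FALSE)
  }
  if (!length(plans)) {
    out <- list(part_dilution = empty_wl(), oligo_pooling = empty_wl(),
                lcr_setup = empty_wl(),
                injection_sequence = data.frame(order = integer(0),
                                                construct = character(0)))
    class(out) <- "lcr_worklists"
    return(out)
  }
  if (is.null(names(plans)) || any(!nzchar(names(plans)))) {
    stop("'plans' must be named by construct id")
  }
  if (is.null(layout)) layout <- auto_layout(plans)

  row <- function(src, dest_labware, dest_barcode, dest_well, volume, reagent) {
    data.frame(source_labware = src$labware, source_barcode = src$barcode,
               source_well = src$well, dest_labware = dest_labware,
               dest_barcode = dest_barcode, dest_well = dest_well,
               volume = volume, reagent = reagent, stringsAsFactors = FALSE)
  }
  plate_barcode <- function(name) {
    paste0("BC", toupper(substr(fnv1a32_hex(name), 1, 6)))
  }
  water <- data.frame(labware = "trough", barcode = plate_barcode("trough"),
                      well = "A1", stringsAsFactors = FALSE)

  # stage 1: part dilution to working concentration
  dil_ratio <- target_nM / stock_nM
  if (dil_ratio <= 0 || dil_ratio > 1) stop("target_nM must be in (0, stock_nM]")
  stock_vol <- dilution_volume * dil_ratio
  parts <- layout$parts
  dilution_wells <- data.frame(id = parts$id, labware = "dilution_plate_1",
                               barcode = plate_barcode("dilution_plate_1"),
                               well = parts$well, stringsAsFactors = FALSE)
  part_dilution <- do.call(rbind, lapply(seq_len(nrow(parts)), function(i) {
    rbind(
      row(parts[i, ], "dilution_plate_1", dilution_wells$barcode[1],
          dilution_wells$well[i], stock_vol, parts$id[i]),
      row(water, "dilution_plate_1", dilution_wells$barcode[1],
          dilution_wells$well[i], dilution_volume - stock_vol, "water")
    )
  }))

  # stage 2: per-construct oligo pooling
  cids <- names(plans)
  if (length(cids) > 96L) stop("more than 96 constructs: split the library")
  pool_wells <- data.frame(id = cids, labware = "oligo_pool_plate",
                           barcode = plate_barcode("oligo_pool_plate"),
                           well = wells_96(length(cids)),
                           stringsAsFactors = FALSE)
  oligo_pooling <- do.call(rbind, lapply(seq_along(cids), function(i) {
    bos <- plans[[cids[i]]]
    src <- lookup_well(layout$oligos,
                       vapply(bos, `[[`, character(1), "id"), "oligo(s)")
    do.call(rbind, lapply(seq_len(nrow(src)), function(j) {
      row(src[j, ], "oligo_pool_plate", pool_wells$barcode[1],
          pool_wells$well[i], oligo_volume, src$id[j])
    }))
  }))

  # stage 3: LCR setup (parts + oligo pool + water fill == reaction volume)
  lcr_wells <- data.frame(id = cids, labware = "lcr_plate",
                          barcode = plate_barcode("lcr_plate"),
                          well = wells_96(length(cids)),
                          stringsAsFactors = FALSE)
  lcr_setup <- do.call(rbind, lapply(seq_along(cids), function(i) {
    bos <- plans[[cids[i]]]
    pids <- unique(vapply(bos, function(bo) bo$junction[["upstream"]], character(1)))
    src <- lookup_well(dilution_wells, pids, "part(s)")
    used <- length(pids) * part_volume + oligo_pool_volume
    if (used > reaction_volume) {
      stop("construct ", cids[i], ": transfers (", used,
           " uL) exceed the reaction volume (", reaction_volume, " uL)")
    }
    if (reaction_volume > well_capacity) {
      stop("reaction volume exceeds well capacity")
    }
    rows <- do.call(rbind, lapply(seq_len(nrow(src)), function(j) {
      row(src[j, ], "lcr_plate", lcr_wells$barcode[1], lcr_wells$well[i],
          part_volume, src$id[j])
    }))
    rows <- rbind(rows,
      row(pool_wells[i, c("labware", "barcode", "well")],
          "lcr_plate", lcr_wells$barcode[1], lcr_wells$well[i],
          oligo_pool_volume, paste0("oligo_pool_", cids[i])))
    if (reaction_volume - used > 0) {
      rows <- rbind(rows,
        row(water, "lcr_plate", lcr_wells$barcode[1], lcr_wells$well[i],
            reaction_volume - used, "water"))
    }
    rows
  }))

  injection <- with_seed(seed, sample(cids))
  out <- list(
    part_dilution = part_dilution,
    oligo_pooling = oligo_pooling,
    lcr_setup = lcr_setup,
    injection_sequence = data.frame(order = seq_along(injection),
                                    construct = injection,
                                    stringsAsFactors = FALSE)
  )
  class(out) <- "lcr_worklists"
  out
}

#' @export
print.lcr_worklists <- function(x, ...) {
  cat(sprintf(paste0("<lcr_worklists> %d dilution, %d pooling, %d LCR transfer(s); ",
                     "%d sample(s) in injection sequence\n"),
              nrow(x$part_dilution), nrow(x$oligo_pooling), nrow(x$lcr_setup),
              nrow(x$injection_sequence)))
  invisible(x)
}

#' Write worklists as CSV files
#'
#' Comma-separated, header row, UTF-8, LF line endings; same inputs and
#' seed give byte-identical files.
#'
#' @param worklists An \code{lcr_worklists} object.
#' @param dir Output directory (created if needed).
#' @return Character vector of the files written.
#' @export
write_worklists <- function(worklists, dir) {
  stopifnot(inherits(worklists, "lcr_worklists"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (nm in c("part_dilution", "oligo_pooling", "lcr_setup",
               "injection_sequence")) {
    path <- file.path(dir, paste0(nm, ".csv"))
    con <- file(path, open = "wb") # LF endings on every platform
    utils::write.csv(worklists[[nm]], con, row.names = FALSE, quote = FALSE,
                     eol = "\n")
    close(con)
    paths <- c(paths, path)
  }
  paths
}
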