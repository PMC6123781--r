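# Construct builder: compile a design point plus part registry into an
# annotated circular plasmid record. Coordinates are 0-based half-open on
# the plus strand internally; GenBank output converts convention.

#' Create a DNA part
#'
#' @param id Unique part identifier.
#' @param role One of \code{"backbone"}, \code{"promoter"}, \code{"gene"},
#'   \code{"terminator"}.
#' @param sequence DNA string over A/C/G/T (case-insensitive).
#' @param metadata Optional free-form named list.
#' @return Object of class \code{dna_part}.
#' @export
dna_part <- function(id, role = c("backbone", "promoter", "gene", "terminator"),
                     sequence, metadata = list()) {
  role <- match.arg(role)
  if (!is_string(id) || !nzchar(id)) stop("part 'id' must be a non-empty string")
  sequence <- toupper(as.character(sequence))
  if (!nzchar(sequence)) stop("part '", id, "': empty sequence")
  if (grepl("[^ACGT]", sequence)) {
    stop("part '", id, "': sequence contains characters outside A/C/G/T")
  }
  structure(list(id = id, role = role, sequence = sequence, metadata = metadata),
            class = "dna_part")
}

#' @export
print.dna_part <- function(x, ...) {
  cat(sprintf("<dna_part> %s (%s, %d bp)\n", x$id, x$role, nchar(x$sequence)))
  invisible(x)
}

#' Assemble a part registry
#'
#' @param parts List of [dna_part()] objects.
#' @return Named list of parts (class \code{part_registry}), keyed by id.
#' @export
part_registry <- function(parts) {
  if (inherits(parts, "dna_part")) parts <- list(parts)
  stopifnot(all(vapply(parts, inherits, logical(1), "dna_part")))
  ids <- vapply(parts, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("duplicate part id(s): ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  structure(stats::setNames(parts, ids), class = "part_registry")
}

#' Read parts from a FASTA file
#'
#' Part roles come from a named \code{roles} vector (id -> role) or, if
#' absent, from a second whitespace-separated token on the FASTA header
#' line (e.g. \code{">PAL gene"}).
#'
#' @param path FASTA file of part sequences.
#' @param roles Optional named character vector id -> role.
#' @return A [part_registry()].
#' @export
read_parts_fasta <- function(path, roles = NULL) {
  seqs <- Biostrings::readDNAStringSet(path)
  parts <- lapply(seq_along(seqs), function(i) {
    header <- names(seqs)[i]
    tokens <- strsplit(trimws(header), "\\s+")[[1]]
    id <- tokens[1]
    role <- if (!is.null(roles)) {
      if (is.na(roles[id] %||% NA)) stop("no role given for part '", id, "'")
      unname(roles[id])
    } else if (length(tokens) >= 2) {
      tokens[2]
    } else {
      stop("part '", id, "': role missing from header and 'roles' map")
    }
    dna_part(id, role = role, sequence = as.character(seqs[[i]]))
  })
  part_registry(parts)
}

#' Write a part registry to FASTA
#'
#' Headers carry \code{id role} so [read_parts_fasta()] round-trips.
#'
#' @param registry A [part_registry()].
#' @param path Output path.
#' @export
write_parts_fasta <- function(registry, path) {
  stopifnot(inherits(registry, "part_registry"))
  seqs <- Biostrings::DNAStringSet(vapply(registry, `[[`, character(1), "sequence"))
  names(seqs) <- vapply(registry, function(p) paste(p$id, p$role), character(1))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

# ---- templates --------------------------------------------------------------

#' Define a construct template
#'
#' A template is the ordered slot layout of a plasmid: exactly one backbone
#' slot, then per gene position an optional promoter slot and a gene slot,
#' plus optional fixed parts (e.g. a terminator). Factor-driven slots name
#' the design factor whose level selects the part; the reserved level
#' \code{"none"} omits the slot.
#'
#' @param slots List of slot entries, each a list with \code{type}
#'   (\code{"backbone"}, \code{"promoter"}, \code{"gene"}, \code{"fixed"}),
#'   and \code{factor} (backbone/promoter), \code{position} (gene/promoter)
#'   or \code{part} (fixed) as appropriate.
#' @return Object of class \code{construct_template}.
#' @export
construct_template <- function(slots) {
  types <- vapply(slots, `[[`, character(1), "type")
  if (sum(types == "backbone") != 1L) {
    stop("template must contain exactly one backbone slot")
  }
  structure(list(slots = slots), class = "construct_template")
}

#' Standard single-operon template for an n-gene pathway
#'
#' Backbone first (its vector promoter drives position 1), then for each
#' position the gene, preceded from position 2 onward by the intergenic
#' promoter slot factor \code{promoter_slot<i>}. An optional terminator
#' part closes the operon.
#'
#' @param genes Character vector of gene names (defines n).
#' @param backbone_factor Name of the backbone factor.
#' @param terminator Optional fixed terminator part id.
#' @return A [construct_template()].
#' @export
operon_template <- function(genes, backbone_factor = "backbone",
                            terminator = NULL) {
  n <- length(genes)
  slots <- list(list(type = "backbone", factor = backbone_factor))
  for (i in seq_len(n)) {
    if (i > 1) {
      slots[[length(slots) + 1L]] <-
        list(type = "promoter", factor = paste0("promoter_slot", i), position = i)
    }
    slots[[length(slots) + 1L]] <- list(type = "gene", position = i)
  }
  if (!is.null(terminator)) {
    slots[[length(slots) + 1L]] <- list(type = "fixed", part = terminator)
  }
  construct_template(slots)
}

#' @noRd
template_factor_refs <- function(template) {
  refs <- vapply(template$slots, function(s) s$factor %||% NA_character_,
                 character(1))
  unique(refs[!is.na(refs)])
}

# ---- plasmid records --------------------------------------------------------

#' Create an annotated plasmid record
#'
#' @param id Record identifier.
#' @param sequence Full DNA sequence (plus strand).
#' @param features \code{data.frame} with columns \code{part}, \code{role},
#'   \code{strand} ("+"/"-"), \code{start}, \code{end} (0-based half-open;
#'   an origin-spanning feature has \code{end > nchar(sequence)} and wraps).
#' @param circular Topology flag (default TRUE).
#' @return Object of class \code{plasmid_record}.
#' @export
plasmid_record <- function(id, sequence, features, circular = TRUE) {
  sequence <- toupper(as.character(sequence))
  stopifnot(is.data.frame(features),
            all(c("part", "role", "strand", "start", "end") %in% names(features)))
  if (grepl("[^ACGT]", sequence)) stop("record '", id, "': non-ACGT sequence")
  if (any(features$start < 0) || any(features$end <= features$start)) {
    stop("record '", id, "': invalid feature interval(s)")
  }
  structure(list(id = id, sequence = sequence, features = features,
                 circular = circular),
            class = "plasmid_record")
}

#' @export
print.plasmid_record <- function(x, ...) {
  cat(sprintf("<plasmid_record> %s: %d bp, %s, %d feature(s)\n",
              x$id, nchar(x$sequence),
              if (x$circular) "circular" else "linear", nrow(x$features)))
  invisible(x)
}

#' Extract a feature's sequence from a record
#'
#' Handles origin-spanning features of circular records.
#'
#' @param record A [plasmid_record()].
#' @param i Feature row index.
#' @return DNA string (plus strand of the record).
#' @export
feature_sequence <- function(record, i) {
  f <- record$features[i, ]
  L <- nchar(record$sequence)
  if (f$end <= L) {
    substr(record$sequence, f$start + 1L, f$end)
  } else {
    if (!record$circular) stop("feature ", i, " overruns a linear record")
    paste0(substr(record$sequence, f$start + 1L, L),
           substr(record$sequence, 1L, f$end - L))
  }
}

#' Compile a design point into a plasmid record
#'
#' Concatenates parts in template order: the backbone part selected by the
#' backbone factor level, then genes placed according to the point's
#' ordering, each (from position 2) preceded by the promoter part its slot
#' factor selects — level \code{"none"} omits the slot entirely, changing
#' the operon structure. Assembly is scar-free (ligase cycling reaction
#' junctions are seamless), so the record length is exactly the sum of its
#' part lengths and the features tile \code{[0, L)} without overlap.
#'
#' @param point A [design_point()].
#' @param registry A [part_registry()]; factor levels and gene names must
#'   resolve to part ids.
#' @param template A [construct_template()]; defaults to the space template
#'   carried by \code{space}.
#' @param space Optional [design_space()] supplying the template.
#' @return A circular [plasmid_record()] named after the point's id.
#' @export
compile_construct <- function(point, registry, template = NULL, space = NULL) {
  stopifnot(inherits(point, "design_point"), inherits(registry, "part_registry"))
  if (is.null(template)) template <- space$template
  if (is.null(template)) stop("no construct template given")
  stopifnot(inherits(template, "construct_template"))

  pick_part <- function(id, slot_desc) {
    p <- registry[[id]]
    if (is.null(p)) stop("missing part '", id, "' for ", slot_desc)
    p
  }

  parts <- list()
  for (s in template$slots) {
    if (s$type == "backbone") {
      lv <- point$assignment[[s$factor]]
      if (is.null(lv) || is.na(lv)) stop("point assigns no level to backbone factor '",
                                         s$factor, "'")
      parts[[length(parts) + 1L]] <- pick_part(lv, paste0("backbone slot (level '", lv, "')"))
    } else if (s$type == "promoter") {
      lv <- point$assignment[[s$factor]]
      if (is.null(lv) || is.na(lv)) stop("point assigns no level to promoter factor '",
                                         s$factor, "'")
      if (identical(lv, "none")) next
      parts[[length(parts) + 1L]] <- pick_part(lv, paste0("promoter slot ", s$position,
                                                          " (level '", lv, "')"))
    } else if (s$type == "gene") {
      g <- point$ordering[s$position]
      parts[[length(parts) + 1L]] <- pick_part(g, paste0("gene slot ", s$position))
    } else if (s$type == "fixed") {
      parts[[length(parts) + 1L]] <- pick_part(s$part, "fixed slot")
    } else {
      stop("unknown slot type '", s$type, "'")
    }
  }

  lens <- vapply(parts, function(p) nchar(p$sequence), integer(1))
  ends <- cumsum(lens)
  starts <- ends - lens
  features <- data.frame(
    part = vapply(parts, `[[`, character(1), "id"),
    role = vapply(parts, `[[`, character(1), "role"),
    strand = "+",
    start = starts, end = ends,
    stringsAsFactors = FALSE
  )
  plasmid_record(point$id,
                 paste(vapply(parts, `[[`, character(1), "sequence"),
                       collapse = ""),
                 features, circular = TRUE)
}
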