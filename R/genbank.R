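# Minimal GenBank flat-file writer/parser for annotated plasmid records.
# Internal coordinates are 0-based half-open; on write they convert to the
# format's 1-based closed convention, with origin-spanning features of
# circular records emitted as join(a..L,1..b) locations.

GB_KEY <- c(backbone = "misc_feature", promoter = "promoter",
            gene = "gene", terminator = "terminator")

#' @noRd
gb_location <- function(start, end, L, strand) {
  loc <- if (end <= L) {
    sprintf("%d..%d", start + 1L, end)
  } else {
    sprintf("join(%d..%d,1..%d)", start + 1L, L, end - L)
  }
  if (identical(strand, "-")) loc <- sprintf("complement(%s)", loc)
  loc
}

#' Write a plasmid record as a GenBank flat file
#'
#' @param record A [plasmid_record()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_genbank <- function(record, path) {
  stopifnot(inherits(record, "plasmid_record"))
  L <- nchar(record$sequence)
  lines <- c(
    sprintf("LOCUS       %-16s %d bp    DNA     %-8s SYN 01-JAN-2000",
            record$id, L, if (record$circular) "circular" else "linear"),
    "DEFINITION  synthetic pathway construct.",
    sprintf("ACCESSION   %s", record$id),
    "FEATURES             Location/Qualifiers",
    sprintf("     source          1..%d", L),
    "                     /organism=\"synthetic DNA construct\""
  )
  if (nrow(record$features)) {
    for (i in seq_len(nrow(record$features))) {
      f <- record$features[i, ]
      key <- GB_KEY[f$role]
      if (is.na(key)) key <- "misc_feature"
      lines <- c(lines,
        sprintf("     %-15s %s", key, gb_location(f$start, f$end, L, f$strand)),
        sprintf("                     /label=\"%s\"", f$part),
        sprintf("                     /note=\"role: %s\"", f$role)
      )
    }
  }
  lines <- c(lines, "ORIGIN")
  seq_lc <- tolower(record$sequence)
  for (off in seq(1L, L, by = 60L)) {
    chunk <- substr(seq_lc, off, min(off + 59L, L))
    blocks <- substring(chunk, seq(1L, nchar(chunk), by = 10L),
                        pmin(seq(10L, nchar(chunk) + 9L, by = 10L), nchar(chunk)))
    lines <- c(lines, sprintf("%9d %s", off, paste(blocks, collapse = " ")))
  }
  lines <- c(lines, "//")
  writeLines(lines, path, sep = "\n")
  invisible(path)
}

#' @noRd
parse_gb_location <- function(loc, lineno) {
  strand <- "+"
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc)) {
    body <- sub("^join\\((.*)\\)$", "\\1", loc)
    segs <- strsplit(body, ",", fixed = TRUE)[[1]]
    if (length(segs) != 2L) {
      stop("line ", lineno, ": unsupported join location '", loc, "'")
    }
    a <- as.integer(strsplit(segs[1], "..", fixed = TRUE)[[1]])
    b <- as.integer(strsplit(segs[2], "..", fixed = TRUE)[[1]])
    if (any(is.na(c(a, b))) || b[1] != 1L) {
      stop("line ", lineno, ": cannot parse origin-spanning location '", loc, "'")
    }
    # join(s..L, 1..e): wrap; end is stored past the sequence length
    return(list(start = a[1] - 1L, end = a[2] + b[2], strand = strand, wrap = TRUE))
  }
  ab <- as.integer(strsplit(loc, "..", fixed = TRUE)[[1]])
  if (length(ab) != 2L || any(is.na(ab))) {
    stop("line ", lineno, ": cannot parse location '", loc, "'")
  }
  list(start = ab[1] - 1L, end = ab[2], strand = strand, wrap = FALSE)
}

#' Read a GenBank flat file into a plasmid record
#'
#' Parses the subset of the format [write_genbank()] emits (LOCUS,
#' FEATURES with label/note qualifiers, ORIGIN); the round trip preserves
#' sequence, topology and features.
#'
#' @param path GenBank file path.
#' @return A [plasmid_record()].
#' @export
read_genbank <- function(path) {
  lines <- readLines(path)
  locus_i <- grep("^LOCUS", lines)
  if (!length(locus_i)) stop("line 1: no LOCUS line; not a GenBank file")
  locus <- lines[locus_i[1]]
  toks <- strsplit(trimws(locus), "\\s+")[[1]]
  id <- toks[2]
  len <- suppressWarnings(as.integer(toks[3]))
  if (is.na(len)) stop("line ", locus_i[1], ": cannot parse sequence length in LOCUS")
  circular <- grepl("circular", locus)

  feat_start <- grep("^FEATURES", lines)
  origin_i <- grep("^ORIGIN", lines)
  if (!length(origin_i)) stop("no ORIGIN section found")

  features <- list()
  current <- NULL
  if (length(feat_start)) {
    for (k in seq(feat_start[1] + 1L, origin_i[1] - 1L)) {
      line <- lines[k]
      if (grepl("^     \\S", line)) {
        # new feature line: key + location
        toks <- strsplit(trimws(line), "\\s+")[[1]]
        if (length(toks) < 2L) stop("line ", k, ": malformed feature line")
        if (!is.null(current)) features[[length(features) + 1L]] <- current
        current <- c(list(key = toks[1]),
                     parse_gb_location(toks[2], k),
                     list(label = NA_character_, role = NA_character_))
      } else if (grepl("^\\s+/", line) && !is.null(current)) {
        q <- trimws(line)
        if (grepl("^/label=", q)) {
          current$label <- gsub("^/label=\"?|\"$", "", q)
        } else if (grepl("^/note=\"?role: ", q)) {
          current$role <- gsub("^/note=\"?role: |\"$", "", q)
        }
      }
    }
    if (!is.null(current)) features[[length(features) + 1L]] <- current
  }
  features <- Filter(function(f) f$key != "source", features)

  seq_lines <- lines[seq(origin_i[1] + 1L, length(lines))]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (nchar(sequence) != len) {
    stop("ORIGIN sequence has ", nchar(sequence), " bp but LOCUS declares ", len)
  }

  fdf <- if (length(features)) {
    data.frame(
      part = vapply(features, function(f) f$label %||% NA_character_, character(1)),
      role = vapply(features, function(f) {
        if (!is.na(f$role)) f$role
        else names(GB_KEY)[match(f$key, GB_KEY)] %||% "backbone"
      }, character(1)),
      strand = vapply(features, `[[`, character(1), "strand"),
      start = vapply(features, `[[`, integer(1), "start"),
      end = vapply(features, `[[`, integer(1), "end"),
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(part = character(0), role = character(0), strand = character(0),
               start = integer(0), end = integer(0), stringsAsFactors = FALSE)
  }
  plasmid_record(id, sequence, fdf, circular = circular)
}
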