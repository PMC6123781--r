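# Learn stage: main-effects least-squares analysis of production titers on
# design factors, per-factor F tests of zero effect, factor ranking, and
# translation of the learned pattern into constraints for the next round.

#' Slot-level design table of a library
#'
#' One row per construct: the declared factor levels plus the gene ordering
#' as a categorical \code{gene_order} column.
#'
#' @param library A \code{pathway_library}.
#' @return data.frame with a \code{construct} column; ordinal factor names
#'   are recorded in \code{attr(, "ordinal")}.
#' @export
slot_design <- function(library) {
  stopifnot(inherits(library, "pathway_library"))
  df <- as.data.frame(library)
  attr(df, "ordinal") <- character(0)
  df
}

#' Gene-linked analysis factors of a library
#'
#' Re-expresses each construct in the factor structure the Learn stage
#' models: the ordinal plasmid copy number (rank of the backbone's origin),
#' the promoter strength directly upstream of each gene (the vector
#' promoter for the gene in position 1 — never \code{"none"} there — or the
#' intergenic slot level otherwise, mapped to none/weak/strong), and the
#' gene ordering as a categorical column. Requires the space's backbone
#' factor to carry \code{copy_rank} and \code{promoter} attrs and promoter
#' slots a \code{strength} attr (the shipped example spaces do).
#'
#' @param library A \code{pathway_library}.
#' @param space The source [design_space()].
#' @return data.frame with columns \code{construct}, \code{copy_number}
#'   (integer rank), \code{promoter_<gene>} for each gene, and
#'   \code{gene_order}; \code{attr(, "ordinal")} lists \code{copy_number}.
#' @export
gene_design <- function(library, space) {
  stopifnot(inherits(library, "pathway_library"), inherits(space, "design_space"))
  bb <- space$factors[["backbone"]]
  if (is.null(bb) || is.null(bb$attrs$copy_rank) || is.null(bb$attrs$promoter)) {
    stop("space's backbone factor must carry 'copy_rank' and 'promoter' attrs")
  }
  genes <- space$order_factor$genes
  n <- length(genes)
  slot_strength <- lapply(2:n, function(i) {
    f <- space$factors[[paste0("promoter_slot", i)]]
    if (is.null(f) || is.null(f$attrs$strength)) {
      stop("space must have a promoter_slot", i, " factor with a 'strength' attr")
    }
    f$attrs$strength
  })
  names(slot_strength) <- as.character(2:n)

  pts <- library$points
  df <- data.frame(construct = vapply(pts, `[[`, character(1), "id"),
                   stringsAsFactors = FALSE)
  bb_level <- vapply(pts, function(p) p$assignment[["backbone"]], character(1))
  df$copy_number <- unname(bb$attrs$copy_rank[bb_level])
  for (g in genes) {
    df[[paste0("promoter_", g)]] <- vapply(pts, function(p) {
      pos <- match(g, p$ordering)
      if (pos == 1L) {
        unname(bb$attrs$promoter[p$assignment[["backbone"]]])
      } else {
        lvl <- p$assignment[[paste0("promoter_slot", pos)]]
        unname(slot_strength[[as.character(pos)]][lvl])
      }
    }, character(1))
  }
  df$gene_order <- vapply(pts, function(p) paste(p$ordering, collapse = ">"),
                          character(1))
  attr(df, "ordinal") <- "copy_number"
  df
}

#' Fit a main-effects model of titer on design factors
#'
#' Ordinary least squares of the (by default log10-transformed) titer on
#' the design factors, main effects only: categorical factors enter with
#' sum-to-zero contrasts, ordinal factors as their integer rank. Each
#' factor's significance is the F test of zero effect from the drop-one
#' model comparison. Fitting is on replicate-level responses.
#'
#' @param design data.frame from [slot_design()] or [gene_design()] (a
#'   \code{construct} column plus factor columns; \code{attr(,"ordinal")}
#'   names the ordinal ones).
#' @param measurements data.frame with columns \code{construct},
#'   \code{replicate}, \code{titer} (mg/L, >= 0).
#' @param factors Which design columns to model (default: all).
#' @param transform \code{"log10"} (default) or \code{"identity"}. The
#'   log10 transform uses \code{log10(titer + epsilon)}.
#' @param epsilon Offset guarding zero titers; default: smallest positive
#'   observed titer / 10 (0 if no transform or all titers positive... the
#'   offset is always added under \code{"log10"}).
#' @return Object of class \code{effect_table}: per-factor F statistics,
#'   p-values, degrees of freedom, ordinal direction, sum-to-zero level
#'   effects, plus fit diagnostics (R-squared, residual df) and the
#'   underlying \code{lm} fit.
#' @export
fit_effects <- function(design, measurements,
                        factors = setdiff(names(design), "construct"),
                        transform = c("log10", "identity"),
                        epsilon = NULL) {
  transform <- match.arg(transform)
  stopifnot(is.data.frame(design), is.data.frame(measurements),
            all(c("construct", "titer") %in% names(measurements)))
  if (any(measurements$titer < 0, na.rm = TRUE)) stop("titers must be >= 0")
  unknown <- setdiff(measurements$construct, design$construct)
  if (length(unknown)) {
    stop("measurement construct id(s) not in the library: ",
         paste(unique(unknown), collapse = ", "))
  }
  ordinal <- intersect(attr(design, "ordinal") %||% character(0), factors)
  dat <- merge(measurements, design[, c("construct", factors), drop = FALSE],
               by = "construct", sort = FALSE)

  if (transform == "log10") {
    if (is.null(epsilon)) {
      pos <- dat$titer[dat$titer > 0]
      epsilon <- if (length(pos)) min(pos) / 10 else 1e-6
    }
    dat$.response <- log10(dat$titer + epsilon)
  } else {
    epsilon <- 0
    dat$.response <- dat$titer
  }

  drop_const <- character(0)
  for (f in factors) {
    if (f %in% ordinal) {
      dat[[f]] <- as.numeric(dat[[f]])
      if (length(unique(dat[[f]])) < 2L) drop_const <- c(drop_const, f)
    } else {
      dat[[f]] <- factor(dat[[f]])
      if (nlevels(dat[[f]]) < 2L) drop_const <- c(drop_const, f)
    }
  }
  factors <- setdiff(factors, drop_const)
  if (!length(factors)) stop("no factor varies across the measured constructs")

  contrasts_list <- stats::setNames(
    lapply(setdiff(factors, ordinal), function(f) "contr.sum"),
    setdiff(factors, ordinal)
  )
  fml <- stats::as.formula(paste(".response ~",
                                 paste(sprintf("`%s`", factors), collapse = " + ")))
  fit <- stats::lm(fml, data = dat, contrasts = contrasts_list)

  if (fit$rank < length(stats::coef(fit))) {
    aliased <- names(which(is.na(stats::coef(fit))))
    stop("rank-deficient design: aliased coefficient(s) ",
         paste(aliased, collapse = ", "),
         "; remove or merge the corresponding factor(s)")
  }
  if (stats::df.residual(fit) < 1L) {
    stop("no residual degrees of freedom: the model saturates the data")
  }

  # zero-noise inputs (simulator interpolation checks) trigger R's
  # "essentially perfect fit" advisories; the F table is still exact
  muffle_perfect_fit <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      if (grepl("perfect fit", conditionMessage(w))) invokeRestart("muffleWarning")
    })
  }
  dr <- muffle_perfect_fit(stats::drop1(fit, test = "F"))
  terms_tab <- dr[-1L, , drop = FALSE] # first row is <none>
  term_names <- gsub("`", "", rownames(terms_tab))

  effects <- list()
  direction <- stats::setNames(rep(NA_real_, length(factors)), factors)
  cf <- stats::coef(fit)
  for (f in factors) {
    if (f %in% ordinal) {
      nm <- if (f %in% names(cf)) f else sprintf("`%s`", f)
      slope <- unname(cf[[nm]])
      effects[[f]] <- c(slope = slope)
      direction[f] <- sign(slope)
    } else {
      lev <- levels(dat[[f]])
      idx <- sprintf("%s%d", f, seq_len(length(lev) - 1L))
      if (!all(idx %in% names(cf))) {
        idx <- sprintf("`%s`%d", f, seq_len(length(lev) - 1L))
      }
      vals <- cf[idx]
      eff <- c(vals, -sum(vals))
      names(eff) <- lev
      effects[[f]] <- eff
    }
  }

  tab <- data.frame(
    factor = term_names,
    kind = ifelse(term_names %in% ordinal, "ordinal", "categorical"),
    df = terms_tab$Df,
    F = terms_tab$`F value`,
    p = terms_tab$`Pr(>F)`,
    direction = unname(direction[term_names]),
    stringsAsFactors = FALSE
  )
  # keep declaration order
  tab <- tab[match(factors, tab$factor), , drop = FALSE]
  rownames(tab) <- NULL

  structure(
    list(table = tab, effects = effects,
         r_squared = muffle_perfect_fit(summary(fit)$r.squared),
         df_residual = stats::df.residual(fit),
         transform = transform, epsilon = epsilon,
         dropped_constant = drop_const, model = fit, data = dat),
    class = "effect_table"
  )
}

#' @export
print.effect_table <- function(x, digits = 4, ...) {
  cat(sprintf("<effect_table> main-effects least squares on %s titer\n",
              if (x$transform == "log10") "log10" else "untransformed"))
  tab <- x$table
  tab$F <- signif(tab$F, digits)
  tab$p <- signif(tab$p, digits)
  print(tab, row.names = FALSE)
  cat(sprintf("R-squared %.3f on %d residual df\n", x$r_squared, x$df_residual))
  if (length(x$dropped_constant)) {
    cat("constant factor(s) dropped:", paste(x$dropped_constant, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.effect_table <- function(object, ...) {
  summary(object$model, ...)
}

#' Rank factors by significance
#'
#' Ascending p-value of the F test of zero effect; ties keep declaration
#' order (stable sort).
#'
#' @param effects An \code{effect_table}.
#' @return Character vector of factor names, most significant first.
#' @export
rank_factors <- function(effects) {
  stopifnot(inherits(effects, "effect_table"))
  tab <- effects$table
  tab$factor[order(tab$p)] # order() is stable: ties keep declaration order
}

#' Define a rule-propagation policy
#'
#' Maps the Learn result onto next-round constraint actions: a significant
#' ordinal factor is fixed at its beneficial extreme; the most significant
#' per-gene promoter factor has its gene pinned to position 1 (always
#' directly downstream of the vector promoter); genes flagged non-limiting
#' by an auxiliary indicator are pinned to the last position with a reduced
#' promoter menu; everything else stays free.
#'
#' @param alpha Significance threshold in (0,1), default 0.05.
#' @param ordinal_map Named character: model factor -> space factor it is
#'   derived from (default \code{c(copy_number = "backbone")}).
#' @param last_slot_menu Function(levels, strength) -> reduced level subset
#'   for the slot feeding the last (non-limiting) gene; default keeps the
#'   no-promoter level and the strongest promoter.
#' @return Object of class \code{rule_policy}.
#' @export
rule_policy <- function(alpha = 0.05,
                        ordinal_map = c(copy_number = "backbone"),
                        last_slot_menu = NULL) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("'alpha' must be in (0, 1)")
  }
  if (is.null(last_slot_menu)) {
    last_slot_menu <- function(levels, strength) {
      keep_none <- levels[strength[levels] == "none"]
      strongest <- levels[strength[levels] == "strong"]
      c(keep_none, strongest)
    }
  }
  structure(list(alpha = alpha, ordinal_map = ordinal_map,
                 last_slot_menu = last_slot_menu),
            class = "rule_policy")
}

#' Flag genes whose expression is not limiting
#'
#' A gene is non-limiting when its pathway intermediate accumulates to high
#' levels in every construct (e.g. cinnamic acid, the product of the first
#' enzyme, observed at high relative levels across a whole library): its
#' enzyme is active enough even at the lowest expression settings tested.
#'
#' @param measurements data.frame with \code{construct} and the
#'   \code{column} holding the intermediate signal.
#' @param gene Gene whose product the intermediate reports on.
#' @param column Column name (default \code{"intermediate"}).
#' @param threshold The gene is flagged iff every construct's median signal
#'   is >= this value.
#' @return \code{gene} if flagged, else \code{character(0)}.
#' @export
flag_non_limiting <- function(measurements, gene, column = "intermediate",
                              threshold) {
  stopifnot(is.data.frame(measurements), column %in% names(measurements))
  med <- tapply(measurements[[column]], measurements$construct, stats::median,
                na.rm = TRUE)
  if (all(med >= threshold)) gene else character(0)
}

#' Propagate learned design rules into next-round constraints
#'
#' Applies a [rule_policy()] to an \code{effect_table} fitted on
#' [gene_design()] factors:
#' \itemize{
#'   \item the most significant ordinal factor (if p < alpha) fixes its
#'     source space factor at the level at the beneficial extreme of the
#'     ordinal rank (ties broken toward a \code{"strong"} promoter attr,
#'     then declaration order);
#'   \item the most significant per-gene promoter factor (if p < alpha)
#'     pins that gene at position 1, guaranteeing a promoter directly
#'     upstream;
#'   \item genes in \code{non_limiting} are pinned at the last position and
#'     the promoter slot feeding that position is restricted to the
#'     policy's reduced menu;
#'   \item all other factors are left free — no constraint emitted.
#' }
#' With nothing significant the result is an empty constraint set (the
#' space is unchanged).
#'
#' @param effects An \code{effect_table} from [fit_effects()] on
#'   [gene_design()] columns.
#' @param space The source [design_space()].
#' @param policy A [rule_policy()].
#' @param non_limiting Character vector of genes flagged by an auxiliary
#'   indicator (see [flag_non_limiting()]).
#' @return A [constraint_set()].
#' @examples
#' \dontrun{
#' cs <- propagate_rules(et, space, rule_policy(), non_limiting = "PAL")
#' count_designs(apply_constraints(space, cs))
#' }
#' @export
propagate_rules <- function(effects, space, policy = rule_policy(),
                            non_limiting = character(0)) {
  stopifnot(inherits(effects, "effect_table"), inherits(space, "design_space"),
            inherits(policy, "rule_policy"))
  tab <- effects$table
  genes <- space$order_factor$genes
  n <- length(genes)
  bad_genes <- setdiff(non_limiting, genes)
  if (length(bad_genes)) {
    stop("non_limiting gene(s) not in the space: ", paste(bad_genes, collapse = ", "))
  }
  unknown_map <- setdiff(unname(policy$ordinal_map), names(space$factors))
  if (length(unknown_map)) {
    stop("policy ordinal_map references unknown space factor(s): ",
         paste(unknown_map, collapse = ", "))
  }

  fixed_levels <- list()
  fixed_positions <- integer(0)
  allowed_levels <- list()
  ranked <- rank_factors(effects)

  # rule (a): strongest significant ordinal factor -> fix source factor at
  # its beneficial extreme
  ord_sig <- tab$factor[tab$kind == "ordinal" & tab$p < policy$alpha]
  ord_sig <- ranked[ranked %in% ord_sig]
  if (length(ord_sig)) {
    f <- ord_sig[1]
    target <- policy$ordinal_map[[f]]
    if (is.null(target)) stop("policy has no ordinal_map entry for '", f, "'")
    sf <- space$factors[[target]]
    rank_map <- sf$attrs$copy_rank
    if (is.null(rank_map)) stop("space factor '", target, "' lacks a copy_rank attr")
    dir <- tab$direction[tab$factor == f]
    extreme <- if (!is.na(dir) && dir < 0) min(rank_map) else max(rank_map)
    cand <- names(rank_map)[rank_map == extreme]
    if (length(cand) > 1L && !is.null(sf$attrs$promoter)) {
      strong <- cand[sf$attrs$promoter[cand] == "strong"]
      if (length(strong)) cand <- strong
    }
    fixed_levels[[target]] <- cand[1]
  }

  # rule (b): most significant per-gene promoter factor -> pin that gene
  # at position 1 (vector promoter directly upstream)
  prom_factors <- tab$factor[startsWith(tab$factor, "promoter_")]
  prom_genes <- sub("^promoter_", "", prom_factors)
  prom_sig <- tab$factor[tab$factor %in% prom_factors & tab$p < policy$alpha]
  prom_sig <- ranked[ranked %in% prom_sig]
  prom_sig <- prom_sig[!(sub("^promoter_", "", prom_sig) %in% non_limiting)]
  if (length(prom_sig)) {
    g <- sub("^promoter_", "", prom_sig[1])
    if (g %in% genes) fixed_positions[g] <- 1L
  }

  # rule (d): non-limiting gene(s) pinned at the end, reduced promoter menu
  # on the slot feeding that position
  if (length(non_limiting)) {
    pos <- n
    for (g in non_limiting) {
      fixed_positions[g] <- pos
      slot <- paste0("promoter_slot", pos)
      sf <- space$factors[[slot]]
      if (!is.null(sf) && !is.null(sf$attrs$strength)) {
        menu <- policy$last_slot_menu(sf$levels, sf$attrs$strength)
        menu <- sf$levels[sf$levels %in% menu]
        if (length(menu) && length(menu) < length(sf$levels)) {
          allowed_levels[[slot]] <- menu
        }
      }
      pos <- pos - 1L
    }
  }
  # rule (c): intermediate factors stay free — nothing emitted.

  constraint_set(fixed_levels = fixed_levels, fixed_positions = fixed_positions,
                 allowed_levels = allowed_levels)
}
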