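# Hierarchical category table: leaf families roll up into superfamily /
# class subtotals (Gypsy + Copia = LTR, LTR + non-LTR = retroelements, ...),
# and two species are contrasted by the ratio of their genome-fraction
# percentages.

#' Repeat category hierarchy
#'
#' Parent-child table of repeat categories used to roll leaf families up
#' into subtotals. [silene_hierarchy()] returns the default tree used for
#' the *Silene* survey comparison (retroelements split into LTR
#' {Gypsy {Athila, Ogre, Peabody, Retand}, Copia} and non-LTR {SINE, LINE},
#' plus DNA transposons and tandem repeats).
#'
#' @param node,parent character vectors; `parent` is `NA` for the root.
#' @return a `repeat_hierarchy` tibble with columns `node`, `parent`.
#' @export
repeat_hierarchy <- function(node, parent) {
  stopifnot(length(node) == length(parent))
  if (anyDuplicated(node)) abort("hierarchy nodes must be unique")
  missing_parent <- !is.na(parent) & !(parent %in% node)
  if (any(missing_parent)) {
    abort(sprintf("parent(s) not defined as nodes: %s",
                  paste(unique(parent[missing_parent]), collapse = ", ")))
  }
  structure(tibble(node = node, parent = parent),
            class = c("repeat_hierarchy", class(tibble())))
}

hierarchy_children <- function(hierarchy, node) {
  hierarchy$node[!is.na(hierarchy$parent) & hierarchy$parent == node]
}

# Depth-first post-order so children are resolved before parents.
hierarchy_postorder <- function(hierarchy) {
  roots <- hierarchy$node[is.na(hierarchy$parent)]
  out <- character(0)
  visit <- function(n) {
    for (ch in hierarchy_children(hierarchy, n)) visit(ch)
    out <<- c(out, n)
  }
  for (r in roots) visit(r)
  out
}

hierarchy_depth <- function(hierarchy) {
  depth <- stats::setNames(rep(NA_integer_, nrow(hierarchy)), hierarchy$node)
  for (n in hierarchy$node[order(is.na(hierarchy$parent), decreasing = TRUE)]) {
    p <- hierarchy$parent[hierarchy$node == n]
    depth[n] <- if (is.na(p)) 0L else depth[p] + 1L
  }
  depth
}

# Resolve copies / percent for every node of the hierarchy from the rows
# supplied for one species. A node with its own supplied row keeps that
# value (printed-style independent count) and propagates it upward; the
# rollup over its children is reported alongside and a discrepancy between
# the two is flagged, not resolved.
resolve_species <- function(rows, hierarchy) {
  rows <- as_tibble(rows)
  if (!"copies" %in% names(rows) && "copies_per_genome" %in% names(rows)) {
    rows$copies <- rows$copies_per_genome
  }
  if (!"percent" %in% names(rows) && "percent_of_genome" %in% names(rows)) {
    rows$percent <- rows$percent_of_genome
  }
  stopifnot(all(c("family", "copies", "percent") %in% names(rows)))
  unknown <- setdiff(rows$family, hierarchy$node)
  if (length(unknown) > 0) {
    abort(sprintf("famil%s not in hierarchy: %s",
                  if (length(unknown) == 1) "y" else "ies",
                  paste(unknown, collapse = ", ")))
  }
  nodes <- hierarchy_postorder(hierarchy)
  val <- stats::setNames(rep(NA_real_, length(nodes)), nodes)
  pct <- val
  roll <- val
  roll_pct <- val
  for (n in nodes) {
    ch <- hierarchy_children(hierarchy, n)
    ch <- ch[!is.na(val[ch])]
    if (length(ch) > 0) {
      roll[n] <- sum(val[ch])
      roll_pct[n] <- sum(pct[ch])
    }
    i <- which(rows$family == n)
    if (length(i) > 0) {
      val[n] <- rows$copies[i[1]]
      pct[n] <- rows$percent[i[1]]
    } else {
      val[n] <- roll[n]
      pct[n] <- roll_pct[n]
    }
  }
  tibble(family = nodes, copies = unname(val), percent = unname(pct),
         copies_rollup = unname(roll),
         rollup_discrepancy = !is.na(val) & !is.na(roll) & val != roll)
}

#' Build the hierarchical two-species comparison table
#'
#' Rolls per-family abundance rows up the category hierarchy for one or two
#' species and, for two, appends the cross-species expansion ratio
#' (percent A / percent B, [compare_fractions()] convention: 0 when both
#' are 0, infinite expansion signalled when only B is 0). Subtotals are
#' summed from unrounded child values, never from rounded percentages; a
#' node supplied with its own independent count *and* a differing child
#' rollup keeps both, with `rollup_discrepancy` flagged.
#'
#' Families present in only one species get copies = 0 and percent = 0 on
#' the absent side.
#'
#' @param estimates_a,estimates_b per-family rows for each species: tibbles
#'   with `family`, `copies` (or `copies_per_genome`) and `percent` (or
#'   `percent_of_genome`), e.g. from [estimate_abundance()]. `estimates_b`
#'   may be `NULL` for a single-species rollup.
#' @param hierarchy a [repeat_hierarchy()]; defaults to
#'   [silene_hierarchy()].
#' @param ratio_decimals half-up rounding of the ratio column.
#' @return a `comparison_table` tibble: `family`, `depth`, per-species
#'   `copies_*`, `percent_*`, rollup columns, and `ratio_a_over_b` for two
#'   species.
#' @export
build_table <- function(estimates_a, estimates_b = NULL,
                        hierarchy = silene_hierarchy(), ratio_decimals = 2) {
  if (nrow(as_tibble(estimates_a)) == 0 &&
      (is.null(estimates_b) || nrow(as_tibble(estimates_b)) == 0)) {
    return(structure(tibble(family = character(), depth = integer()),
                     class = c("comparison_table", class(tibble()))))
  }
  depth <- hierarchy_depth(hierarchy)
  a <- resolve_species(estimates_a, hierarchy)
  two <- !is.null(estimates_b)
  if (two) {
    b <- resolve_species(estimates_b, hierarchy)
    # a family screened in one species only counts 0 on the absent side
    a_missing <- is.na(a$copies) & !is.na(b$copies)
    b_missing <- is.na(b$copies) & !is.na(a$copies)
    a$copies[a_missing] <- 0
    a$percent[a_missing] <- 0
    b$copies[b_missing] <- 0
    b$percent[b_missing] <- 0
  }
  out <- tibble(
    family = a$family,
    depth = unname(depth[a$family]),
    copies_a = a$copies,
    percent_a = a$percent,
    copies_rollup_a = a$copies_rollup,
    rollup_discrepancy_a = a$rollup_discrepancy
  )
  if (two) {
    out$copies_b <- b$copies
    out$percent_b <- b$percent
    out$copies_rollup_b <- b$copies_rollup
    out$rollup_discrepancy_b <- b$rollup_discrepancy
    keep <- !(is.na(out$copies_a) & is.na(out$copies_b))
    out <- out[keep, ]
    out$ratio_a_over_b <- compare_fractions(out$percent_a, out$percent_b,
                                            decimals = ratio_decimals)
  } else {
    out <- out[!is.na(out$copies_a), ]
  }
  # table order: depth-first pre-order of the hierarchy
  pre <- hierarchy_preorder(hierarchy)
  out <- out[order(match(out$family, pre)), ]
  structure(out, class = c("comparison_table", class(tibble())))
}

hierarchy_preorder <- function(hierarchy) {
  roots <- hierarchy$node[is.na(hierarchy$parent)]
  out <- character(0)
  visit <- function(n) {
    out <<- c(out, n)
    for (ch in hierarchy_children(hierarchy, n)) visit(ch)
  }
  for (r in roots) visit(r)
  out
}

#' @export
print.comparison_table <- function(x, ...) {
  cat("<comparison_table>\n")
  y <- as_tibble(x)
  if (nrow(y) > 0) {
    y$family <- paste0(strrep("  ", y$depth), y$family)
  }
  print(y, n = nrow(y))
  invisible(x)
}

#' Bar chart of cross-species expansion ratios
#'
#' Ratios above 1 mark families more expanded in species A, below 1 more
#' expanded in species B; infinite ratios (absent from B) are dropped with
#' a message.
#'
#' @param object a `comparison_table` from [build_table()] with two species.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot comparison_table
#' @export
autoplot.comparison_table <- function(object, ...) {
  stopifnot("ratio_a_over_b" %in% names(object))
  df <- as_tibble(object)
  if (any(is.infinite(df$ratio_a_over_b))) {
    message("dropping families with infinite expansion ratio from the plot")
    df <- df[is.finite(df$ratio_a_over_b), ]
  }
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$family, .data$ratio_a_over_b),
    y = .data$ratio_a_over_b)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "genome-fraction ratio (A / B)")
}
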