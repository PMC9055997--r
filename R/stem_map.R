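#' Construct a stem map
#'
#' A stem map is a data frame of individually mapped trees inside a
#' rectangular stand, one row per stem, carrying the stand geometry as
#' attributes. Required columns are \code{tree_id}, \code{species_name},
#' \code{x}, \code{y} (local Cartesian metres, origin at the south-west
#' corner), \code{dbh} (diameter at breast height, cm), \code{th} (total
#' height, m), \code{hcb} (height to crown base, m) and \code{cw} (crown
#' width, m). The constructor derives \code{species_group} (six groups, see
#' \code{\link{classify_species_group}}) and \code{growth_stage}
#' (\code{"sapling"} for 1 <= DBH < 5 cm, \code{"adult"} for DBH >= 5 cm)
#' when absent, and validates every row.
#'
#' Row-level invariants: \code{dbh >= 1} (the marking threshold),
#' \code{0 < hcb < th}, \code{cw > 0}, and coordinates inside the stand
#' rectangle.
#'
#' @param trees data frame with the columns listed above.
#' @param stand_width,stand_height stand dimensions in metres.
#' @param plot_size side length of the square grid cells, metres.
#' @param group_table named character vector mapping species names to group
#'   codes, see \code{\link{default_species_groups}}.
#' @param mode \code{"strict"} stops on the first batch of invalid rows;
#'   \code{"lenient"} drops them with a message.
#' @return An object of class \code{stem_map} (a data frame).
#' @export
stem_map <- function(trees, stand_width = 120, stand_height = 140,
                     plot_size = 20,
                     group_table = default_species_groups(),
                     mode = c("strict", "lenient")) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(trees), stand_width > 0, stand_height > 0,
            plot_size > 0)
  required <- c("tree_id", "species_name", "x", "y", "dbh", "th", "hcb", "cw")
  missing_cols <- setdiff(required, names(trees))
  if (length(missing_cols)) {
    stop("stem map is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  trees <- as.data.frame(trees, stringsAsFactors = FALSE)
  trees$tree_id <- as.character(trees$tree_id)
  if (anyDuplicated(trees$tree_id)) stop("tree_id values must be unique")
  num_cols <- c("x", "y", "dbh", "th", "hcb", "cw")
  trees[num_cols] <- lapply(trees[num_cols], as.numeric)

  if (is.null(trees$species_group)) {
    trees$species_group <- classify_species_group(trees$species_name,
                                                  group_table)
  }
  trees$growth_stage <- ifelse(trees$dbh < 5, "sapling", "adult")

  bad <- .invalid_tree_rows(trees, stand_width, stand_height)
  if (length(bad$rows)) {
    msg <- paste0("invalid tree record(s):\n",
                  paste(sprintf("  row %d (tree_id %s): %s", bad$rows,
                                trees$tree_id[bad$rows], bad$why),
                        collapse = "\n"))
    if (mode == "strict") stop(msg)
    message(sprintf("dropping %d invalid row(s)", length(bad$rows)))
    trees <- trees[-bad$rows, , drop = FALSE]
  }
  rownames(trees) <- NULL
  structure(trees,
            stand_width = stand_width, stand_height = stand_height,
            plot_size = plot_size,
            class = c("stem_map", "data.frame"))
}

# row indices violating the record invariants, with one reason per row
.invalid_tree_rows <- function(trees, stand_width, stand_height) {
  why <- character(nrow(trees))
  flag <- function(cond, reason) {
    cond[is.na(cond)] <- TRUE
    why[cond & !nzchar(why)] <<- reason
  }
  flag(trees$dbh < 1, "dbh below 1 cm marking threshold")
  flag(!(trees$hcb > 0 & trees$hcb < trees$th), "hcb not in (0, th)")
  flag(trees$cw <= 0, "cw must be positive")
  flag(trees$x < 0 | trees$x > stand_width |
         trees$y < 0 | trees$y > stand_height,
       "coordinates outside the stand rectangle")
  rows <- which(nzchar(why))
  list(rows = rows, why = why[rows])
}

#' @export
print.stem_map <- function(x, ...) {
  cat(sprintf("Stem map: %d trees, %g x %g m stand, %g m grid\n",
              nrow(x), attr(x, "stand_width"), attr(x, "stand_height"),
              attr(x, "plot_size")))
  if (!is.null(x$plot_id)) {
    cat(sprintf("  %d occupied plots\n", length(unique(x$plot_id))))
  }
  cat(sprintf("  dbh %.2f-%.2f cm, cw %.2f-%.2f m, %d species groups\n",
              min(x$dbh), max(x$dbh), min(x$cw), max(x$cw),
              length(unique(x$species_group))))
  invisible(x)
}

#' Default species-name to species-group table
#'
#' The six groups used throughout: the five most numerous species of the
#' study system -- \emph{Betula luminifera} (BL), \emph{Platycarya
#' strobilacea} (PS), \emph{Pinus massoniana} (PM), \emph{Liquidambar
#' formosana} (LF), \emph{Populus davidiana} (PD) -- and \code{Others} for
#' every unlisted name.
#'
#' @return Named character vector (names are species, values group codes).
#' @export
default_species_groups <- function() {
  c("Betula luminifera"      = "BL",
    "Platycarya strobilacea" = "PS",
    "Pinus massoniana"       = "PM",
    "Liquidambar formosana"  = "LF",
    "Populus davidiana"      = "PD")
}

#' Map species names to the six species groups
#'
#' Names absent from \code{group_table} fall back to \code{"Others"}; the
#' mapping is total and never errors.
#'
#' @param species_name character vector of species names.
#' @param group_table named character vector, names are species names.
#' @return Character vector of group codes.
#' @export
classify_species_group <- function(species_name,
                                   group_table = default_species_groups()) {
  out <- unname(group_table[as.character(species_name)])
  out[is.na(out)] <- "Others"
  out
}

#' Read a stem map from delimited text
#'
#' Reads a CSV or TSV file (auto-detected from the extension; \code{.tsv}
#' and \code{.txt} are tab-separated) with a header row, optionally renames
#' columns through \code{column_map}, and validates it through
#' \code{\link{stem_map}}.
#'
#' @param path file path.
#' @param column_map optional named character vector mapping canonical
#'   column names to the file's column names, e.g.
#'   \code{c(dbh = "DBH_cm", th = "Height")}.
#' @inheritParams stem_map
#' @return A \code{stem_map}.
#' @export
read_stem_map <- function(path, column_map = NULL,
                          stand_width = 120, stand_height = 140,
                          plot_size = 20, mode = c("strict", "lenient")) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (!is.null(column_map)) {
    missing <- setdiff(unname(column_map), names(raw))
    if (length(missing)) {
      stop("column_map refers to absent column(s): ",
           paste(missing, collapse = ", "))
    }
    for (canon in names(column_map)) {
      names(raw)[names(raw) == column_map[[canon]]] <- canon
    }
  }
  stem_map(raw, stand_width = stand_width, stand_height = stand_height,
           plot_size = plot_size, mode = mode)
}

#' Write a stem map as CSV
#'
#' @param x a \code{stem_map}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_stem_map <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' Assign trees to grid plots
#'
#' Grids the stand into square cells of side \code{plot_size} and assigns
#' each tree to its cell. Cells are half-open \code{[k*s, (k+1)*s)} with the
#' final row/column closed on the upper stand edge, so every in-stand
#' coordinate belongs to exactly one cell. Adds \code{grid_x}, \code{grid_y}
#' (0-based column/row indices counted from the origin) and \code{plot_id}.
#'
#' @param x a \code{stem_map}.
#' @return \code{x} with plot columns set.
#' @export
assign_plots <- function(x) {
  stopifnot(inherits(x, "stem_map"))
  s <- attr(x, "plot_size")
  nx <- ceiling(attr(x, "stand_width") / s)
  ny <- ceiling(attr(x, "stand_height") / s)
  gx <- pmin(floor(x$x / s), nx - 1L)
  gy <- pmin(floor(x$y / s), ny - 1L)
  x$grid_x <- as.integer(gx)
  x$grid_y <- as.integer(gy)
  x$plot_id <- sprintf("p%d_%d", x$grid_x, x$grid_y)
  x
}

#' Number of grid cells of a stem map
#' @param x a \code{stem_map}.
#' @return Integer count of cells (occupied or not).
#' @export
n_grid_cells <- function(x) {
  s <- attr(x, "plot_size")
  as.integer(ceiling(attr(x, "stand_width") / s) *
               ceiling(attr(x, "stand_height") / s))
}

#' Dominant-tree rule: largest n stems by DBH
#'
#' Returns a rule function selecting, within one plot, the \code{n}
#' largest-DBH trees (all trees when fewer than \code{n} are present), ties
#' broken by \code{tree_id}. With the default \code{n = 4} on 20 x 20 m
#' plots this is the common 100-stems-per-hectare dominant-tree convention.
#'
#' @param n number of dominant trees per plot.
#' @return A function mapping a plot's tree data frame to a logical vector.
#' @export
dominant_top_n <- function(n = 4) {
  force(n)
  function(trees) {
    ord <- order(-trees$dbh, trees$tree_id)
    keep <- ord[seq_len(min(n, nrow(trees)))]
    seq_len(nrow(trees)) %in% keep
  }
}

#' Stand covariates of one plot
#'
#' Computes, from the trees of a single plot: stand density \code{den}
#' (stems/ha, count divided by the plot area in ha), mean total height
#' \code{mth} (m), mean dominant height \code{mdh} (m, mean TH of the trees
#' selected by \code{dominant_rule}), mean dominant DBH \code{mdd} (cm, used
#' by the relative-diameter competition index), and the Shannon diversity
#' \code{shn} of species-group stem proportions (natural log, nats).
#'
#' @param trees data frame of one plot's trees (must be non-empty).
#' @param dominant_rule rule function, see \code{\link{dominant_top_n}}.
#' @param plot_area_ha plot area in hectares (0.04 for 20 x 20 m).
#' @return One-row data frame with \code{n_trees}, \code{den}, \code{mth},
#'   \code{mdh}, \code{mdd}, \code{shn}.
#' @export
stand_covariates <- function(trees, dominant_rule = dominant_top_n(4),
                             plot_area_ha = 0.04) {
  if (!nrow(trees)) stop("empty plot: stand covariates are undefined")
  dom <- dominant_rule(trees)
  p <- table(trees$species_group) / nrow(trees)
  data.frame(
    n_trees = nrow(trees),
    den = nrow(trees) / plot_area_ha,
    mth = mean(trees$th),
    mdh = mean(trees$th[dom]),
    mdd = mean(trees$dbh[dom]),
    shn = -sum(p * log(p))
  )
}

#' Per-plot stand covariates of a stem map
#'
#' Applies \code{\link{stand_covariates}} to every occupied plot. Empty grid
#' cells are simply absent from the result (they hold no trees to
#' summarise).
#'
#' @param x a \code{stem_map}; plots are assigned first when absent.
#' @inheritParams stand_covariates
#' @return Data frame, one row per occupied plot, keyed by \code{plot_id}.
#' @export
plot_summaries <- function(x, dominant_rule = dominant_top_n(4)) {
  if (is.null(x$plot_id)) x <- assign_plots(x)
  area_ha <- attr(x, "plot_size")^2 / 1e4
  pieces <- lapply(split(as.data.frame(x), x$plot_id), function(tr) {
    cbind(plot_id = tr$plot_id[1], grid_x = tr$grid_x[1],
          grid_y = tr$grid_y[1],
          stand_covariates(tr, dominant_rule, area_ha))
  })
  out <- do.call(rbind, pieces)
  out <- out[order(out$grid_x, out$grid_y), ]
  rownames(out) <- NULL
  out
}

#' Split a stem map into calibration and validation sets by plot
#'
#' Plot-level random partition: trees of one plot always travel together.
#' The calibration set receives \code{round(fraction * n)} of the \code{n}
#' occupied plots, drawn with a seeded generator so the split is exactly
#' reproducible; the two parts together restore the input.
#'
#' @param x a \code{stem_map} (plots assigned automatically).
#' @param fraction proportion of plots assigned to calibration, in (0, 1).
#' @param seed integer seed for the plot draw.
#' @return List with \code{stem_map} elements \code{calibration} and
#'   \code{validation}, plus \code{calibration_plots} and
#'   \code{validation_plots}.
#' @export
split_plots <- function(x, fraction = 0.8, seed = 1) {
  stopifnot(inherits(x, "stem_map"))
  if (!(fraction > 0 && fraction < 1)) {
    stop("fraction must lie strictly between 0 and 1")
  }
  if (is.null(x$plot_id)) x <- assign_plots(x)
  plots <- sort(unique(x$plot_id))
  if (length(plots) < 2) stop("need at least 2 occupied plots to split")
  n_cal <- round(fraction * length(plots))
  n_cal <- min(max(n_cal, 1L), length(plots) - 1L)
  # local RNG scope: restore the caller's RNG state afterwards
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  set.seed(seed)
  cal_plots <- sort(sample(plots, n_cal))
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  take <- function(ids) {
    sub <- x[x$plot_id %in% ids, , drop = FALSE]
    rownames(sub) <- NULL
    attributes(sub)[c("stand_width", "stand_height", "plot_size", "class")] <-
      attributes(x)[c("stand_width", "stand_height", "plot_size", "class")]
    sub
  }
  list(calibration = take(cal_plots),
       validation = take(setdiff(plots, cal_plots)),
       calibration_plots = cal_plots,
       validation_plots = setdiff(plots, cal_plots))
}
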