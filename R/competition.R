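#' Inter-tree distance with optional edge correction
#'
#' Euclidean distance between mapped stems, either in the plane
#' (\code{geometry = "euclidean"}) or on the torus obtained by wrapping the
#' stand rectangle (\code{geometry = "torus"}, minimum-image convention).
#' The torus metric is the computational equivalent of the classical
#' translation (8-copy tiling) edge correction for any search radius below
#' half the smaller stand dimension: the nearest translated image of a
#' neighbour is exactly the minimum-image neighbour.
#'
#' @param x1,y1,x2,y2 coordinates in metres (vectorised).
#' @param geometry \code{"euclidean"} or \code{"torus"}.
#' @param stand_width,stand_height stand dimensions (required for torus).
#' @return Numeric vector of distances in metres.
#' @export
tree_distance <- function(x1, y1, x2, y2,
                          geometry = c("euclidean", "torus"),
                          stand_width = NULL, stand_height = NULL) {
  geometry <- match.arg(geometry)
  dx <- x2 - x1
  dy <- y2 - y1
  if (geometry == "torus") {
    stopifnot(!is.null(stand_width), !is.null(stand_height))
    dx <- dx - stand_width * round(dx / stand_width)
    dy <- dy - stand_height * round(dy / stand_height)
  }
  sqrt(dx^2 + dy^2)
}

# Displacements from a subject to every other tree under an edge-correction
# scheme. Returns index (into the stand), dx, dy, dist. Under "tiling" each
# neighbour contributes its nearest translated image only (images of the
# subject itself are never competitors); under "torus" the minimum-image
# displacement; under "none" the raw displacement.
.neighbour_displacements <- function(i, xs, ys, w, h,
                                     edge = c("torus", "tiling", "none")) {
  edge <- match.arg(edge)
  idx <- seq_along(xs)[-i]
  dx <- xs[idx] - xs[i]
  dy <- ys[idx] - ys[i]
  if (edge == "torus") {
    dx <- dx - w * round(dx / w)
    dy <- dy - h * round(dy / h)
  } else if (edge == "tiling") {
    # explicit 3 x 3 translation copies; keep each neighbour's closest image
    best_d2 <- rep(Inf, length(idx))
    bdx <- dx
    bdy <- dy
    for (ox in c(-w, 0, w)) {
      for (oy in c(-h, 0, h)) {
        tdx <- dx + ox
        tdy <- dy + oy
        d2 <- tdx^2 + tdy^2
        upd <- d2 < best_d2
        best_d2[upd] <- d2[upd]
        bdx[upd] <- tdx[upd]
        bdy[upd] <- tdy[upd]
      }
    }
    dx <- bdx
    dy <- bdy
  }
  data.frame(index = idx, dx = dx, dy = dy, dist = sqrt(dx^2 + dy^2))
}

#' Competitors within a fixed search radius
#'
#' All other trees whose (edge-corrected) distance to the subject is at most
#' \code{radius}; the boundary is closed. An empty result is legitimate for
#' an isolated subject.
#'
#' @param subject_id \code{tree_id} of the subject tree.
#' @param stand a \code{stem_map}.
#' @param radius search radius in metres (default 5).
#' @param edge edge-correction scheme: minimum-image \code{"torus"}
#'   (default), explicit 3 x 3 \code{"tiling"}, or \code{"none"}.
#' @return Data frame with \code{tree_id}, \code{dbh}, \code{distance},
#'   ordered by distance then \code{tree_id}.
#' @export
find_competitors_radius <- function(subject_id, stand, radius = 5,
                                    edge = c("torus", "tiling", "none")) {
  edge <- match.arg(edge)
  i <- match(as.character(subject_id), stand$tree_id)
  if (is.na(i)) stop("subject tree not found in stand: ", subject_id)
  nb <- .neighbour_displacements(i, stand$x, stand$y,
                                 attr(stand, "stand_width"),
                                 attr(stand, "stand_height"), edge)
  nb <- nb[nb$dist <= radius, , drop = FALSE]
  out <- data.frame(tree_id = stand$tree_id[nb$index],
                    dbh = stand$dbh[nb$index],
                    distance = nb$dist)
  out[order(out$distance, out$tree_id), , drop = FALSE]
}

#' Competitors as the nearest tree per quadrant
#'
#' Directional competitor rule: the plane around the subject is divided
#' into \code{n} equal half-open angular sectors (for the default
#' \code{n = 4}, the Cartesian quadrants \code{[0, 90)}, \code{[90, 180)},
#' ... degrees) and the nearest tree of each sector is taken. When a sector
#' holds no tree, the overall next-nearest unused tree is substituted so
#' exactly \code{n} competitors are returned. Distance ties break on
#' \code{tree_id}, making the selection deterministic.
#'
#' @inheritParams find_competitors_radius
#' @param n number of competitors (and sectors).
#' @return Data frame with \code{tree_id}, \code{dbh}, \code{distance},
#'   \code{quadrant} (1-based sector, NA for substituted trees).
#' @export
find_competitors_quadrant <- function(subject_id, stand, n = 4,
                                      edge = c("torus", "tiling", "none")) {
  edge <- match.arg(edge)
  i <- match(as.character(subject_id), stand$tree_id)
  if (is.na(i)) stop("subject tree not found in stand: ", subject_id)
  if (nrow(stand) - 1L < n) {
    stop(sprintf("stand holds %d potential competitors; %d required",
                 nrow(stand) - 1L, n))
  }
  nb <- .neighbour_displacements(i, stand$x, stand$y,
                                 attr(stand, "stand_width"),
                                 attr(stand, "stand_height"), edge)
  ang <- atan2(nb$dy, nb$dx)          # (-pi, pi]
  ang <- ang %% (2 * pi)              # [0, 2*pi)
  sector <- pmin(floor(ang / (2 * pi / n)), n - 1) + 1L
  id <- stand$tree_id[nb$index]
  ord <- order(nb$dist, id)
  chosen <- integer(0)
  quad <- integer(0)
  for (q in seq_len(n)) {
    cand <- ord[sector[ord] == q]
    if (length(cand)) {
      chosen <- c(chosen, cand[1])
      quad <- c(quad, q)
    }
  }
  # substitute overall next-nearest unused trees for empty sectors
  fill <- setdiff(ord, chosen)
  n_missing <- n - length(chosen)
  if (n_missing > 0) {
    chosen <- c(chosen, fill[seq_len(n_missing)])
    quad <- c(quad, rep(NA_integer_, n_missing))
  }
  out <- data.frame(tree_id = id[chosen],
                    dbh = stand$dbh[nb$index[chosen]],
                    distance = nb$dist[chosen],
                    quadrant = quad)
  out[order(out$distance, out$tree_id), , drop = FALSE]
}

#' Hegyi competition index of one subject tree
#'
#' The size-ratio, distance-weighted sum
#' \deqn{HG_i = \sum_j D_j / (D_i (L_{ij} + 1))}
#' over the subject's competitors, with DBH in cm and distance in metres;
#' the +1 m offset keeps the term finite for coincident stems. An empty
#' competitor set gives 0.
#'
#' @param dbh_subject subject DBH, cm.
#' @param dbh_competitors competitor DBHs, cm (possibly empty).
#' @param distances competitor distances, m (same length).
#' @return Dimensionless index value.
#' @export
hegyi_index <- function(dbh_subject, dbh_competitors, distances) {
  stopifnot(dbh_subject > 0, length(dbh_competitors) == length(distances))
  if (!length(dbh_competitors)) return(0)
  sum(dbh_competitors / (dbh_subject * (distances + 1)))
}

#' One competition index of one plot
#'
#' Plot-level indices over the trees of a plot. Distance-independent:
#' \code{SD} (sum of DBH, cm), \code{SDD} (sum of DBH over the plot's
#' dominant trees), \code{SRD} (sum of DBH / mean dominant DBH,
#' dimensionless), \code{SBA} (sum of basal area, m^2). Distance-dependent:
#' \code{SHGN} and \code{SHGR}, sums over the plot's trees of their Hegyi
#' index with competitors found by the fixed-number
#' (\code{\link{find_competitors_quadrant}}) or fixed-radius
#' (\code{\link{find_competitors_radius}}) rule. Subjects are only the
#' plot's own trees, but competitors are searched over the whole stand
#' under the configured edge correction, so trees of adjacent plots (or
#' translated images) compete across plot boundaries.
#'
#' @param plot_trees data frame of the plot's trees (rows of \code{stand}).
#' @param stand the full \code{stem_map}.
#' @param index one of \code{"SD"}, \code{"SDD"}, \code{"SRD"},
#'   \code{"SBA"}, \code{"SHGN"}, \code{"SHGR"}.
#' @param radius fixed-radius search radius, m (SHGR).
#' @param n_competitors competitor count (SHGN).
#' @param edge edge-correction scheme for the distance-dependent indices.
#' @param dominant_rule dominant-tree rule (SDD, SRD), see
#'   \code{\link{dominant_top_n}}.
#' @return Scalar index value.
#' @export
plot_competition_index <- function(plot_trees, stand,
                                   index = c("SD", "SDD", "SRD", "SBA",
                                             "SHGN", "SHGR"),
                                   radius = 5, n_competitors = 4,
                                   edge = c("torus", "tiling", "none"),
                                   dominant_rule = dominant_top_n(4)) {
  index <- match.arg(index)
  edge <- match.arg(edge)
  if (!nrow(plot_trees)) stop("empty plot: competition index undefined")
  d <- plot_trees$dbh
  switch(index,
    SD  = sum(d),
    SDD = sum(d[dominant_rule(plot_trees)]),
    SRD = sum(d) / mean(d[dominant_rule(plot_trees)]),
    SBA = sum(pi * (d / 200)^2),
    SHGN = sum(vapply(seq_len(nrow(plot_trees)), function(k) {
      cmp <- find_competitors_quadrant(plot_trees$tree_id[k], stand,
                                       n = n_competitors, edge = edge)
      hegyi_index(d[k], cmp$dbh, cmp$distance)
    }, numeric(1))),
    SHGR = sum(vapply(seq_len(nrow(plot_trees)), function(k) {
      cmp <- find_competitors_radius(plot_trees$tree_id[k], stand,
                                     radius = radius, edge = edge)
      hegyi_index(d[k], cmp$dbh, cmp$distance)
    }, numeric(1)))
  )
}

#' All six competition indices for every occupied plot
#'
#' @param stand a \code{stem_map} (plots assigned automatically).
#' @inheritParams plot_competition_index
#' @return Data frame, one row per occupied plot, with \code{plot_id},
#'   \code{SD}, \code{SDD}, \code{SRD}, \code{SBA}, \code{SHGN},
#'   \code{SHGR} and \code{MDD} (mean dominant DBH, cm).
#' @export
competition_indices <- function(stand, radius = 5, n_competitors = 4,
                                edge = c("torus", "tiling", "none"),
                                dominant_rule = dominant_top_n(4)) {
  edge <- match.arg(edge)
  if (is.null(stand$plot_id)) stand <- assign_plots(stand)
  pieces <- lapply(split(as.data.frame(stand), stand$plot_id), function(tr) {
    vals <- vapply(c("SD", "SDD", "SRD", "SBA", "SHGN", "SHGR"),
                   function(ix) plot_competition_index(
                     tr, stand, ix, radius = radius,
                     n_competitors = n_competitors, edge = edge,
                     dominant_rule = dominant_rule),
                   numeric(1))
    cbind(data.frame(plot_id = tr$plot_id[1], grid_x = tr$grid_x[1],
                     grid_y = tr$grid_y[1]),
          as.data.frame(as.list(vals)),
          MDD = mean(tr$dbh[dominant_rule(tr)]))
  })
  out <- do.call(rbind, pieces)
  out <- out[order(out$grid_x, out$grid_y), ]
  rownames(out) <- NULL
  out
}
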