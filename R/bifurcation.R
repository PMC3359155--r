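# Bifurcation diagrams over the degradation rate lambda and the CPEB1
# activation rate k5.
#
# Continuation is warm-started root tracking on a dense grid (the
# quartic and one_d levels expose cheap solves; reduced3/full reuse the
# previous grid point's roots as Newton seeds), not pseudo-arclength.
# Saddle-nodes are recorded where the root count changes by two and
# refined by bisection on the bracketing interval.

set_sweep_param <- function(params, name, value) {
  p <- unclass(params)
  if (name == "lambda") {
    p$lambda1 <- value
    p$lambda2 <- value
  } else if (name %in% param_fields) {
    p[[name]] <- value
  } else {
    loop_error(sprintf("unknown sweep parameter '%s'", name),
               "loop_schema_error")
  }
  validate_params(p)
}

#' Sweep a parameter and track the fixed points
#'
#' @param params base `loop_params`.
#' @param name swept parameter: `"lambda"` (sets both degradation rates)
#'   or any rate-constant field such as `"k5"`.
#' @param grid ascending numeric grid of parameter values.
#' @param level model level at which fixed points are solved.
#' @param fit inversion fit (one_d level); refitted per grid point when
#'   omitted, since the map changes with the parameter.
#' @param refine_saddle_nodes bisect root-count changes to refine the
#'   saddle-node locations (1e-3 relative).
#' @return a `bifurcation_diagram`: list with `points` (data frame:
#'   `param_value`, `branch_id`, `XT`, `XP`, `stability`,
#'   `leading_eigenvalue`, `model_level`), `grid`, `param` (+ unit
#'   convention uM/s), `saddle_nodes`, `level`.
#' @export
sweep_bifurcation <- function(params, name, grid, level = "quartic",
                              fit = NULL, refine_saddle_nodes = TRUE) {
  level <- match.arg(level, model_levels)
  if (!length(grid)) loop_error("empty sweep grid", "loop_invalid_input")
  if (is.unsorted(grid)) grid <- sort(grid)
  sets <- vector("list", length(grid))
  prev <- NULL
  for (i in seq_along(grid)) {
    p_i <- set_sweep_param(params, name, grid[i])
    f_i <- if (level == "one_d") fit %||% fit_inversion(p_i) else NULL
    seeds <- if (!is.null(prev) && level %in% c("reduced3", "full")) {
      attr(prev, "seed_states")
    }
    fps <- solve_fixed_points(p_i, level, fit = f_i, extra_seeds = seeds)
    attr(fps, "seed_states") <- if (level == "full") {
      attr(fps, "states")
    } else if (level == "reduced3") {
      lapply(seq_len(nrow(fps)), function(k) c(fps$XT[k], fps$XP[k], fps$YP[k]))
    }
    sets[[i]] <- fps
    prev <- fps
  }
  pts <- do.call(rbind, lapply(seq_along(grid), function(i) {
    s <- sets[[i]]
    if (!nrow(s)) return(NULL)
    data.frame(param_value = grid[i], branch_id = NA_integer_,
               XT = s$XT, XP = s$XP, stability = s$stability,
               leading_eigenvalue = s$leading_eigenvalue,
               model_level = level, stringsAsFactors = FALSE)
  }))
  pts <- assign_branches(pts)
  counts <- vapply(sets, nrow, 0L)
  sn <- numeric(0)
  for (i in seq_len(length(grid) - 1)) {
    if (abs(counts[i + 1] - counts[i]) == 2) {
      sn <- c(sn, if (refine_saddle_nodes) {
        refine_sn(params, name, grid[i], grid[i + 1], counts[i], level, fit)
      } else (grid[i] + grid[i + 1]) / 2)
    }
  }
  structure(list(points = pts, grid = grid, param = name,
                 saddle_nodes = sn, level = level, sets = sets,
                 base_params = params),
            class = "bifurcation_diagram")
}

# nearest-continuation branch matching on |dXT| / (1 + XT)
assign_branches <- function(pts, threshold = 0.25) {
  if (is.null(pts) || !nrow(pts)) return(pts)
  pts <- pts[order(pts$param_value, pts$XT), ]
  vals <- unique(pts$param_value)
  next_id <- 1L
  open <- list()  # branch_id -> last XT
  for (v in vals) {
    idx <- which(pts$param_value == v)
    used <- character(0)
    for (j in idx) {
      best <- NULL; bestd <- threshold
      for (b in setdiff(names(open), used)) {
        d <- abs(pts$XT[j] - open[[b]]) / (1 + pts$XT[j])
        if (d < bestd) { best <- b; bestd <- d }
      }
      if (is.null(best)) {
        best <- as.character(next_id)
        next_id <- next_id + 1L
      }
      pts$branch_id[j] <- as.integer(best)
      open[[best]] <- pts$XT[j]
      used <- c(used, best)
    }
    open <- open[names(open) %in% c(used)]
  }
  pts
}

refine_sn <- function(params, name, lo, hi, n_lo, level, fit) {
  count_at <- function(v) {
    p <- set_sweep_param(params, name, v)
    f <- if (level == "one_d") fit %||% fit_inversion(p) else NULL
    nrow(solve_fixed_points(p, level, fit = f))
  }
  while ((hi - lo) > 1e-3 * max(abs(hi), 1e-300)) {
    mid <- sqrt(lo * hi)
    if (count_at(mid) == n_lo) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' @export
print.bifurcation_diagram <- function(x, ...) {
  cat(sprintf(
    "<bifurcation_diagram> %s sweep, %d grid points, level %s, %d saddle-node(s)\n",
    x$param, length(x$grid), x$level, length(x$saddle_nodes)))
  invisible(x)
}

#' Contiguous bistable interval of a diagram
#'
#' @param diagram a `bifurcation_diagram` with at least two grid points.
#' @return list with `lo`, `hi` (parameter values bounding the widest
#'   contiguous region with three fixed points), `decades`
#'   (`log10(hi/lo)`), and `empty`.
#' @export
bistable_range <- function(diagram) {
  if (length(diagram$grid) < 2) {
    loop_error("need at least two grid points", "loop_invalid_input")
  }
  counts <- vapply(diagram$sets, nrow, 0L)
  bi <- counts >= 3
  if (!any(bi)) {
    return(list(lo = NA_real_, hi = NA_real_, decades = 0, empty = TRUE))
  }
  r <- rle(bi)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- which(r$values)
  widths <- log10(diagram$grid[ends[runs]] / diagram$grid[starts[runs]])
  k <- runs[which.max(widths)]
  lo <- diagram$grid[starts[k]]; hi <- diagram$grid[ends[k]]
  list(lo = lo, hi = hi, decades = log10(hi / lo), empty = FALSE)
}

#' Branch-wise agreement between diagrams at different model levels
#'
#' Aligns the lower/unstable/upper branches at each shared grid point
#' and reports the maximum relative XT discrepancy per branch.  Verdict
#' is `"match"` when every branch agrees within `tol` everywhere both
#' diagrams have the branch.
#'
#' @param diagrams list of `bifurcation_diagram`s on the same grid and
#'   parameter.
#' @param tol relative tolerance for the verdict (default 15%).
#' @return list with `per_branch` (max relative discrepancy matrix,
#'   levels x branches), `verdict`, and `pairwise_max`.
#' @export
diagram_agreement <- function(diagrams, tol = 0.15) {
  if (length(diagrams) < 2) {
    loop_error("need at least two diagrams", "loop_invalid_input")
  }
  g0 <- diagrams[[1]]$grid
  for (d in diagrams) {
    if (length(d$grid) != length(g0) || any(d$grid != g0) ||
        d$param != diagrams[[1]]$param) {
      loop_error("diagrams must share grid and swept parameter",
                 "loop_invalid_input")
    }
  }
  branch3 <- function(s) {
    st <- s$XT[s$stability == "stable"]
    un <- s$XT[s$stability == "unstable"]
    c(lower = if (length(st)) min(st) else NA_real_,
      unstable = if (length(un)) max(un) else NA_real_,
      upper = if (length(st)) max(st) else NA_real_)
  }
  ref <- diagrams[[1]]
  lv <- vapply(diagrams, function(d) d$level, "")
  per <- matrix(NA_real_, length(diagrams), 3,
                dimnames = list(lv, c("lower", "unstable", "upper")))
  for (k in seq_along(diagrams)) {
    dmax <- c(lower = 0, unstable = 0, upper = 0)
    for (i in seq_along(g0)) {
      b1 <- branch3(ref$sets[[i]])
      b2 <- branch3(diagrams[[k]]$sets[[i]])
      # relative where the branch is appreciable, absolute (0.5 uM floor)
      # near the basal state; a branch present in only one diagram is an
      # outright mismatch
      rel <- abs(b2 - b1) / pmax(abs(b1), 0.5)
      rel[is.na(b1) & is.na(b2)] <- 0
      rel[xor(is.na(b1), is.na(b2))] <- Inf
      dmax <- pmax(dmax, rel)
    }
    per[k, ] <- dmax
  }
  pairwise_max <- max(per, na.rm = TRUE)
  list(per_branch = per,
       verdict = if (pairwise_max <= tol) "match" else "mismatch",
       pairwise_max = pairwise_max)
}
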