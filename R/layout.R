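#' Layout parameters
#'
#' The layout is a damped spring-electrical system extended with two group
#' terms: members of a group are additionally attracted toward their group
#' centroid (gain `group_attraction_gain`), and node pairs belonging to
#' different groups repel more strongly (gain `group_repulsion_gain`), so
#' that groups contract and separate geometrically. Coordinates are
#' abstract units (consumers scale for rendering); the final configuration
#' is translated so the global centroid sits at the origin.
#'
#' @param spring_constant spring stiffness along edges (default 0.1).
#' @param rest_length natural edge length in layout units (default 50).
#' @param repulsion_constant pairwise inverse-square repulsion strength
#'   (default 5000).
#' @param group_attraction_gain >= 1; multiplies the centroid pull on
#'   grouped nodes (default 3).
#' @param group_repulsion_gain >= 1; multiplies repulsion between nodes of
#'   different groups (default 2).
#' @param gravity stiffness of a weak spring pulling every node toward the
#'   origin (default 0.02). Gravity gives disconnected networks a bounded
#'   equilibrium: without it, components repel each other indefinitely and
#'   the system never reaches the convergence tolerance.
#' @param damping velocity damping factor in (0,1) (default 0.9).
#' @param step_size integration step (default 0.3; chosen with the default
#'   force constants for stable, reasonably fast settling).
#' @param max_iter iteration cap (default 500).
#' @param convergence_tol stop when mean per-node displacement in one
#'   iteration falls below this (default 1e-3 units); 0 disables early
#'   stopping.
#' @param seed integer seed for the initial uniform-disc placement.
#' @return a named list of class `modnet_layout_params`.
#' @export
layout_params <- function(spring_constant = 0.1, rest_length = 50,
                          repulsion_constant = 5000,
                          group_attraction_gain = 3.0,
                          group_repulsion_gain = 2.0,
                          gravity = 0.02,
                          damping = 0.9, step_size = 0.3,
                          max_iter = 500L, convergence_tol = 1e-3,
                          seed = 42L) {
  stopifnot(spring_constant > 0, rest_length > 0, repulsion_constant >= 0,
            group_attraction_gain >= 1, group_repulsion_gain >= 1,
            gravity >= 0, damping > 0, damping < 1, step_size > 0,
            max_iter >= 0, convergence_tol >= 0)
  structure(list(spring_constant = spring_constant,
                 rest_length = rest_length,
                 repulsion_constant = repulsion_constant,
                 group_attraction_gain = group_attraction_gain,
                 group_repulsion_gain = group_repulsion_gain,
                 gravity = gravity,
                 damping = damping, step_size = step_size,
                 max_iter = as.integer(max_iter),
                 convergence_tol = convergence_tol,
                 seed = as.integer(seed)),
            class = "modnet_layout_params")
}

# run expr with a private RNG stream, restoring the caller's state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

group_of <- function(net) {
  grp <- stats::setNames(rep(NA_character_, n_nodes(net)), node_ids(net))
  for (gr in net$groups) grp[gr$members] <- gr$id
  grp
}

init_layout <- function(net, params) {
  ids <- sort(node_ids(net))
  n <- length(ids)
  coords <- with_seed(params$seed, {
    r <- params$rest_length * sqrt(n) / 2 * sqrt(stats::runif(n))
    th <- stats::runif(n, 0, 2 * pi)
    cbind(x = r * cos(th), y = r * sin(th))
  })
  # deterministic jitter for coincident points (possible at n = 1 duplicates)
  dup <- duplicated(round(coords, 9))
  if (any(dup))
    coords[dup, ] <- coords[dup, , drop = FALSE] +
      0.01 * params$rest_length * (seq_len(sum(dup)))
  rownames(coords) <- ids
  coords <- sweep(coords, 2, colMeans(coords))
  if (n == 1) coords[1, ] <- c(0, 0)
  structure(list(coords = coords,
                 velocity = matrix(0, n, 2, dimnames = list(ids, NULL)),
                 iteration = 0L, converged = n <= 1,
                 group_geometry = list()),
            class = "modnet_layout")
}

#' @export
print.modnet_layout <- function(x, ...) {
  cat(sprintf("layout state: %d nodes, iteration %d, %sconverged\n",
              nrow(x$coords), x$iteration, if (x$converged) "" else "not "))
  invisible(x)
}

layout_forces <- function(coords, edges, grp, params) {
  n <- nrow(coords)
  frc <- matrix(0, n, 2)
  if (n > 1) {
    dx <- outer(coords[, 1], coords[, 1], "-")
    dy <- outer(coords[, 2], coords[, 2], "-")
    d2 <- dx * dx + dy * dy
    d2[d2 < 1e-12] <- 1e-12
    d <- sqrt(d2)
    # repulsion ~ C / d^2, scaled up across distinct groups
    gain <- matrix(1, n, n)
    if (any(!is.na(grp))) {
      diffg <- outer(grp, grp, function(a, b) !is.na(a) & !is.na(b) & a != b)
      gain[diffg] <- params$group_repulsion_gain
    }
    rep_mag <- gain * params$repulsion_constant / d2
    diag(rep_mag) <- 0
    frc[, 1] <- rowSums(rep_mag * dx / d)
    frc[, 2] <- rowSums(rep_mag * dy / d)
    # springs along edges toward rest length
    if (nrow(edges)) {
      iu <- edges$iu; iv <- edges$iv
      ex <- coords[iv, 1] - coords[iu, 1]
      ey <- coords[iv, 2] - coords[iu, 2]
      ed <- sqrt(ex * ex + ey * ey)
      ed[ed < 1e-9] <- 1e-9
      f <- params$spring_constant * (ed - params$rest_length)
      fx <- f * ex / ed; fy <- f * ey / ed
      for (k in seq_along(iu)) {
        frc[iu[k], 1] <- frc[iu[k], 1] + fx[k]
        frc[iu[k], 2] <- frc[iu[k], 2] + fy[k]
        frc[iv[k], 1] <- frc[iv[k], 1] - fx[k]
        frc[iv[k], 2] <- frc[iv[k], 2] - fy[k]
      }
    }
    # weak gravity toward the origin bounds disconnected components
    frc <- frc - params$gravity * coords
    # centroid pull on grouped nodes
    for (gid in unique(grp[!is.na(grp)])) {
      m <- which(grp == gid)
      cx <- mean(coords[m, 1]); cy <- mean(coords[m, 2])
      frc[m, 1] <- frc[m, 1] + params$spring_constant *
        params$group_attraction_gain * (cx - coords[m, 1])
      frc[m, 2] <- frc[m, 2] + params$spring_constant *
        params$group_attraction_gain * (cy - coords[m, 2])
    }
  }
  frc
}

advance_layout <- function(state, net, params, n_steps, stop_on_converge) {
  ids <- rownames(state$coords)
  grp <- group_of(net)[ids]
  edges <- net$edges
  edges$iu <- match(edges$u, ids)
  edges$iv <- match(edges$v, ids)
  coords <- state$coords
  vel <- state$velocity
  it <- state$iteration
  converged <- state$converged
  step <- 0L
  while (step < n_steps) {
    frc <- layout_forces(coords, edges, grp, params)
    vel <- (vel + params$step_size * frc) * params$damping
    disp <- params$step_size * vel
    coords <- coords + disp
    # re-center every iteration: forces are translation-invariant, and
    # doing it here (not once at the end) keeps split runs bitwise equal
    # to unsplit runs
    coords <- sweep(coords, 2, colMeans(coords))
    it <- it + 1L
    step <- step + 1L
    mean_disp <- mean(sqrt(rowSums(disp^2)))
    converged <- params$convergence_tol > 0 && mean_disp < params$convergence_tol
    if (converged && stop_on_converge) break
  }
  state$coords <- coords
  state$velocity <- vel
  state$iteration <- it
  state$converged <- converged
  state
}

finalize_layout <- function(state, net, padding) {
  # coords are already origin-centered (init and every iteration re-center)
  state$group_geometry <- lapply(net$groups, function(gr)
    group_outline(state, gr$members, gr$shape, padding = padding))
  state
}

#' Run the group-aware force-directed layout
#'
#' Deterministic for a given (network, params, seed): initial positions are
#' drawn from a seeded uniform disc, then the damped spring-electrical
#' system (see [layout_params()]) is iterated until the mean per-node
#' displacement drops below `convergence_tol` or `max_iter` is reached.
#' The returned coordinates are centroid-normalized to the origin and the
#' outline geometry of every group is computed.
#'
#' @param net a non-empty `modnet_network`.
#' @param params a [layout_params()] list.
#' @param padding outline padding for group geometry (default
#'   `rest_length / 5`).
#' @return a `modnet_layout` state: `coords` (n x 2 matrix, rownames =
#'   node ids), `velocity`, `iteration`, `converged`, `group_geometry`.
#' @export
run_layout <- function(net, params = layout_params(), padding = NULL) {
  stopifnot_network(net)
  if (n_nodes(net) == 0) stop("network is empty", call. = FALSE)
  if (is.null(padding)) padding <- params$rest_length / 5
  state <- init_layout(net, params)
  if (nrow(state$coords) > 1)
    state <- advance_layout(state, net, params, params$max_iter, TRUE)
  finalize_layout(state, net, padding)
}

#' Advance a layout by exactly n iterations
#'
#' Continues a state produced by [run_layout()] or [step_layout()] on the
#' same network for exactly `n` iterations using the parameters given
#' *now*, which is the dynamic-reconfiguration contract: parameters may
#' change between calls and take effect immediately. With constant
#' parameters (and early stopping disabled via `convergence_tol = 0`),
#' splitting a run into chunks reproduces the unsplit run exactly.
#'
#' @param state a `modnet_layout`.
#' @param net the same network the state was produced from.
#' @param params a [layout_params()] list (possibly changed).
#' @param n number of iterations (>= 0; 0 is the identity).
#' @param padding outline padding (default `rest_length / 5`).
#' @return the advanced `modnet_layout`.
#' @export
step_layout <- function(state, net, params, n, padding = NULL) {
  stopifnot_network(net)
  if (!inherits(state, "modnet_layout"))
    stop("expected a modnet_layout state", call. = FALSE)
  if (!setequal(rownames(state$coords), node_ids(net)))
    stop("layout state does not match the network's node set", call. = FALSE)
  if (is.null(padding)) padding <- params$rest_length / 5
  if (n > 0) state <- advance_layout(state, net, params, n, FALSE)
  finalize_layout(state, net, padding)
}

#' Layout animation frames
#'
#' Runs the layout while snapshotting the state every `every` iterations;
#' the final frame is always included and equals the [run_layout()] result
#' for the same inputs.
#'
#' @param net a `modnet_network`.
#' @param params a [layout_params()] list.
#' @param every snapshot period (>= 1).
#' @param padding outline padding.
#' @return list of `modnet_layout` states.
#' @export
layout_frames <- function(net, params = layout_params(), every = 25L,
                          padding = NULL) {
  stopifnot_network(net)
  if (every < 1) stop("every must be >= 1", call. = FALSE)
  if (is.null(padding)) padding <- params$rest_length / 5
  state <- init_layout(net, params)
  out <- list()
  done <- nrow(state$coords) <= 1
  while (!done && state$iteration < params$max_iter) {
    n <- min(every, params$max_iter - state$iteration)
    state <- advance_layout(state, net, params, n, TRUE)
    out[[length(out) + 1L]] <- finalize_layout(state, net, padding)
    done <- state$converged || state$iteration >= params$max_iter
  }
  if (!length(out)) out <- list(finalize_layout(state, net, padding))
  out
}

#' Group outline geometry
#'
#' Computes the display outline for a set of member coordinates:
#' `rectangle` is the axis-aligned bounding box, `circle` the smallest
#' centroid-centered circle covering the members, `convex_hull` the convex
#' hull of the member coordinates; all padded outward by `padding`.
#' Singleton groups yield a degenerate (point buffered by padding) outline.
#'
#' @param state a `modnet_layout` (or any list with a `coords` matrix).
#' @param members member node ids.
#' @param shape `"rectangle"`, `"circle"` or `"convex_hull"`.
#' @param padding outward padding in layout units (default 0).
#' @return list with `shape`, `centroid` (length-2), and `outline`
#'   (matrix of outline vertices; for `circle`, attribute `radius` is set
#'   and the outline is a 64-gon approximation).
#' @export
group_outline <- function(state, members, shape = c("convex_hull",
                                                    "rectangle", "circle"),
                          padding = 0) {
  shape <- match.arg(shape)
  co <- state$coords[members, , drop = FALSE]
  centroid <- colMeans(co)
  if (shape == "rectangle") {
    lo <- apply(co, 2, min) - padding
    hi <- apply(co, 2, max) + padding
    outline <- rbind(c(lo[1], lo[2]), c(hi[1], lo[2]),
                     c(hi[1], hi[2]), c(lo[1], hi[2]))
  } else if (shape == "circle") {
    r <- max(sqrt(rowSums(sweep(co, 2, centroid)^2))) + padding
    th <- seq(0, 2 * pi, length.out = 65)[-65]
    outline <- cbind(centroid[1] + r * cos(th), centroid[2] + r * sin(th))
    attr(outline, "radius") <- r
  } else {
    hull <- grDevices::chull(co[, 1], co[, 2])
    pts <- co[hull, , drop = FALSE]
    if (padding > 0 && nrow(pts) >= 1) {
      dir <- sweep(pts, 2, centroid)
      len <- sqrt(rowSums(dir^2))
      len[len < 1e-12] <- 1
      pts <- pts + padding * dir / len
    }
    outline <- unname(pts)
  }
  dimnames(outline) <- list(NULL, c("x", "y"))
  list(shape = shape, centroid = unname(centroid), outline = outline)
}
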