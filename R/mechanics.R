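#' Physical cell body
#'
#' @param id integer id.
#' @param position numeric 3-vector (um).
#' @param radius sphere radius (um, > 0).
#' @param drag drag coefficient (force h / um, > 0). Identical for all germ
#'   cells by default; only F/drag is identifiable, the stiffness absorbs the
#'   scale.
#' @return a `cell_body` list; `rest_volume` is (4/3) pi r^3.
#' @export
cell_body <- function(id, position, radius, drag = 1) {
  stopifnot(length(position) == 3L, radius > 0, drag > 0)
  structure(list(id = as.integer(id), position = as.numeric(position),
                 radius = radius, drag = drag,
                 rest_volume = 4 / 3 * pi * radius^3),
            class = "cell_body")
}

#' Mechanics parameters
#'
#' @param stiffness_k linear overlap-spring constant (force/um).
#' @param dt_mech mechanics time step (hours). Stability of the explicit Euler
#'   update requires stiffness_k * dt_mech / drag well below 1.
#' @param neighbor_cutoff pair cutoff (um), at least twice the largest cell
#'   radius; `NULL` to derive it from the current radii each step.
#' @param drag common drag coefficient.
#' @return a `force_params` list.
#' @export
force_params <- function(stiffness_k = 20, dt_mech = 0.01,
                         neighbor_cutoff = NULL, drag = 1) {
  stopifnot(stiffness_k > 0, dt_mech > 0, drag > 0,
            is.null(neighbor_cutoff) || neighbor_cutoff > 0)
  structure(list(stiffness_k = stiffness_k, dt_mech = dt_mech,
                 neighbor_cutoff = neighbor_cutoff, drag = drag),
            class = "force_params")
}

#' Pairwise repulsion between two overlapping spheres
#'
#' Reference single-pair implementation of the linear overlap spring: with
#' overlap delta = max(0, r_a + r_b - |x_a - x_b|) the force on `a` is
#' k * delta along the unit vector from `b` to `a`; the force on `b` is its
#' exact negation. Coincident centres repel along a deterministic
#' pseudo-random direction derived from the id pair.
#'
#' @param a,b [cell_body()] objects (a != b).
#' @param p a [force_params()] object.
#' @return numeric 3-vector: force on `a`.
#' @export
pairwise_repulsion <- function(a, b, p) {
  stopifnot(a$id != b$id)
  f <- cpp_repulsion_forces(rbind(a$position, b$position),
                            c(a$radius, b$radius),
                            1L, 2L, p$stiffness_k, c(a$id, b$id))
  f[1L, ]
}

#' Net repulsion forces for a cell collection
#'
#' @param pos n x 3 position matrix (um).
#' @param radius radii (um).
#' @param pairs 2-column integer matrix of interacting pairs (from
#'   [find_neighbors()]).
#' @param p a [force_params()] object.
#' @param ids integer ids (for deterministic handling of coincident centres).
#' @return n x 3 force matrix.
#' @export
repulsion_forces <- function(pos, radius, pairs, p,
                             ids = seq_len(nrow(pos))) {
  cpp_repulsion_forces(pos, radius, pairs[, 1L], pairs[, 2L],
                       p$stiffness_k, as.integer(ids))
}

#' Overdamped forward-Euler position update
#'
#' x <- x + (F / drag) * dt. Aborts when any displacement exceeds half the
#' smallest radius, which signals a too-large time step.
#'
#' @param pos n x 3 position matrix.
#' @param forces n x 3 force matrix.
#' @param p a [force_params()] object.
#' @param radius radii (um), used for the displacement safety check.
#' @return updated position matrix.
#' @export
integrate_positions <- function(pos, forces, p, radius) {
  disp <- forces * (p$dt_mech / p$drag)
  if (nrow(pos)) {
    dmax <- sqrt(max(rowSums(disp^2)))
    if (dmax > 0.5 * min(radius))
      stop(sprintf(
        "mechanics step displacement %.3g um exceeds half the smallest radius (%.3g um); reduce dt_mech",
        dmax, min(radius)), call. = FALSE)
  }
  pos + disp
}

#' Compressed volume of a cell among overlapping neighbours
#'
#' The rest volume minus, for every overlapping neighbour, the spherical cap
#' cut off by the radical plane of the two spheres (for equal radii R at
#' distance d < 2R: cap height h = R - d/2, cap volume pi h^2 (3R - h) / 3).
#' The result is clamped below at `floor_frac` of the rest volume. Mutual
#' intersections of caps are ignored, an approximation appropriate for the
#' moderate overlaps the repulsion force permits.
#'
#' @param cell a [cell_body()].
#' @param neighbors list of [cell_body()] objects within the cutoff.
#' @param floor_frac lower clamp as a fraction of rest volume.
#' @return compressed volume (um^3).
#' @export
compressed_volume <- function(cell, neighbors, floor_frac = 0.05) {
  if (!length(neighbors)) return(cell$rest_volume)
  pos <- rbind(cell$position,
               do.call(rbind, lapply(neighbors, `[[`, "position")))
  rad <- c(cell$radius, vapply(neighbors, `[[`, 0, "radius"))
  m <- length(neighbors)
  frac <- cpp_compressed_fractions(pos, rad, rep(1L, m), seq_len(m) + 1L,
                                   floor_frac)
  frac[1L] * cell$rest_volume
}

#' Compressed volume fractions for a cell collection
#'
#' @param pos n x 3 position matrix.
#' @param radius radii (um).
#' @param pairs 2-column pair matrix.
#' @param floor_frac lower clamp as a fraction of rest volume.
#' @return numeric vector of volume fractions in (0, 1].
#' @export
compressed_fractions <- function(pos, radius, pairs, floor_frac = 0.05) {
  cpp_compressed_fractions(pos, radius, pairs[, 1L], pairs[, 2L], floor_frac)
}

#' Neighbour pairs within a cutoff
#'
#' Uniform-spatial-grid search; identical, as a set of unordered pairs, to the
#' O(n^2) all-pairs scan with centre distance strictly below the cutoff.
#'
#' @param pos n x 3 position matrix.
#' @param cutoff pair cutoff (um, > 0).
#' @return 2-column integer matrix of pair indices (i < j).
#' @export
find_neighbors <- function(pos, cutoff) {
  stopifnot(cutoff > 0)
  cpp_neighbor_pairs(pos, cutoff)
}

#' Radius-aware contact pairs
#'
#' All unordered pairs whose centre distance is below the sum of their radii
#' (plus an optional skin), i.e. the pairs that can exert force or deform one
#' another. Equivalent to filtering the all-pairs scan by the per-pair
#' contact range, but computed with a spatial grid for the ordinary cells and
#' ranged queries for the few large (oocyte) cells.
#'
#' @param pos n x 3 position matrix.
#' @param radius radii (um).
#' @param split_radius cells larger than this are treated as "large".
#' @param skin extra margin added to every contact range (um).
#' @return 2-column integer matrix of pair indices (i < j).
#' @export
contact_pairs <- function(pos, radius, split_radius = 4.5, skin = 0) {
  cpp_contact_pairs(pos, radius, split_radius, skin)
}
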