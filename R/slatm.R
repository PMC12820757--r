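#' SLATM grid specification
#'
#' Defines the element universe and the radial/angular grids for the
#' molecule-level SLATM spectrum: a one-body block (element counts weighted by
#' Z), a London-weighted two-body radial spectrum per unordered element pair,
#' and an Axilrod-Teller-Muto-weighted three-body angular spectrum per
#' (center element, unordered neighbor-element pair) bag.
#'
#' Defaults follow the descriptor's reference implementation conventions:
#' radial grid 0.8..4.8 Angstrom in 0.03 steps with 0.05 Angstrom Gaussian
#' smearing; angular grid 0..pi rad in 0.03 steps with 0.05 rad smearing;
#' 4.8 Angstrom three-body cutoff (applied to both center-neighbor legs).
#'
#' @param universe sorted atomic numbers present in the dataset.
#' @param r_min,r_cut radial grid range, Angstrom.
#' @param dr radial grid step, Angstrom.
#' @param sigma2 two-body Gaussian smearing, Angstrom.
#' @param dtheta angular grid step, rad.
#' @param sigma3 three-body Gaussian smearing, rad.
#' @param cutoff3 three-body distance cutoff, Angstrom.
#' @return object of class `"qd_slatmspec"`.
#' @export
slatm_spec <- function(universe, r_min = 0.8, r_cut = 4.8, dr = 0.03,
                       sigma2 = 0.05, dtheta = 0.03, sigma3 = 0.05,
                       cutoff3 = 4.8) {
  universe <- sort(unique(as.integer(universe)))
  if (!length(universe)) stop("empty element universe", call. = FALSE)
  if (r_min >= r_cut) stop("need r_min < r_cut", call. = FALSE)
  if (dr <= 0 || dtheta <= 0 || sigma2 <= 0 || sigma3 <= 0)
    stop("grid steps and smearings must be > 0", call. = FALSE)
  r_grid <- seq(r_min, r_cut, by = dr)
  t_grid <- seq(0, pi, by = dtheta)
  pairs <- .pair_labels(universe)
  sym <- element_symbol(universe)
  trip_lab <- as.vector(t(outer(sym, pairs$label, paste, sep = "@")))
  # triple bags ordered center-major: for each center element, all pairs
  trips <- expand.grid(pair = seq_len(nrow(pairs)),
                       center = seq_along(universe))[, c(2, 1)]
  labels <- c(paste0("1b_", sym),
              unlist(lapply(pairs$label, function(p)
                paste0("2b_", p, "_", seq_along(r_grid)))),
              unlist(lapply(seq_len(nrow(trips)), function(k)
                paste0("3b_", sym[trips$center[k]], "@",
                       pairs$label[trips$pair[k]], "_",
                       seq_along(t_grid)))))
  structure(list(universe = universe, r_grid = r_grid, t_grid = t_grid,
                 dr = dr, dtheta = dtheta, sigma2 = sigma2, sigma3 = sigma3,
                 cutoff3 = cutoff3, pairs = pairs, trips = trips,
                 labels = labels,
                 length = length(universe) +
                   nrow(pairs) * length(r_grid) +
                   nrow(trips) * length(t_grid)),
            class = "qd_slatmspec")
}

#' @export
print.qd_slatmspec <- function(x, ...) {
  cat("<SLATM spec> universe {",
      paste(element_symbol(x$universe), collapse = ", "),
      "}, ", length(x$r_grid), " radial x ", length(x$t_grid),
      " angular points, vector length ", x$length, "\n", sep = "")
  invisible(x)
}

#' Fit BOB and SLATM layouts on a dataset
#'
#' Convenience wrapper returning both descriptor specifications as
#' deterministic functions of the dataset: the bag layout sized to the
#' dataset's maxima and a SLATM spec over the union of observed elements.
#'
#' @param dataset a [qd_dataset()] or list of molecules.
#' @param ... SLATM grid parameters passed to [slatm_spec()].
#' @return list with elements `bag` and `slatm`.
#' @export
fit_descriptor_space <- function(dataset, ...) {
  mols <- if (inherits(dataset, "qd_dataset")) dataset$molecules else dataset
  if (!length(mols)) stop("empty dataset", call. = FALSE)
  bag <- fit_bag_spec(mols)
  list(bag = bag, slatm = slatm_spec(bag$universe, ...))
}

#' SLATM vector of one molecule
#'
#' Computes the molecule-level SLATM spectrum under a fixed grid spec:
#' \itemize{
#'   \item one-body: per universe element, atom count times Z;
#'   \item two-body: per unordered element pair, the radial spectrum
#'     `S2(r) = sum over pairs Z_i Z_j r_ij^-6 N(r; r_ij, sigma2) dr` with
#'     `N` the normal density, summed over unordered atom pairs (i < j) of
#'     that type;
#'   \item three-body: per (center element, neighbor-pair) bag, the angular
#'     spectrum `S3(theta) = sum over triples Z_i Z_j Z_k
#'     (1 + 3 cos(th_i) cos(th_j) cos(th_k)) / (r_ij r_ik r_jk)^3
#'     N(theta; th_i, sigma3) dtheta`, `th_i` the angle at the center, each
#'     geometric triple counted once per center atom, both center legs within
#'     the cutoff.
#' }
#' Invariant to rigid motion and atom permutation; smooth in the coordinates.
#'
#' @param mol a [molecule()] whose elements lie in the spec universe.
#' @param spec a [slatm_spec()].
#' @return named numeric vector of length `spec$length`.
#' @export
slatm_vector <- function(mol, spec) {
  stopifnot(inherits(mol, "qd_molecule"), inherits(spec, "qd_slatmspec"))
  z <- mol$Z
  if (!all(z %in% spec$universe))
    stop("spec mismatch: molecule ", mol$id,
         " contains elements outside the SLATM universe", call. = FALSE)
  universe <- spec$universe
  n <- length(z)
  one <- vapply(universe, function(u) sum(z == u) * u, numeric(1))

  n_r <- length(spec$r_grid)
  two <- matrix(0, n_r, nrow(spec$pairs))
  if (n > 1L) {
    d <- .pair_dist(mol$coords)
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      zi <- min(z[i], z[j]); zj <- max(z[i], z[j])
      k <- which(spec$pairs$z1 == zi & spec$pairs$z2 == zj)
      r <- d[i, j]
      two[, k] <- two[, k] + z[i] * z[j] * r^-6 *
        stats::dnorm(spec$r_grid, r, spec$sigma2) * spec$dr
    }
  }

  n_t <- length(spec$t_grid)
  three <- matrix(0, n_t, nrow(spec$trips))
  if (n > 2L) {
    d <- .pair_dist(mol$coords)
    for (c_i in seq_len(n)) {
      nb <- setdiff(seq_len(n), c_i)
      nb <- nb[d[c_i, nb] <= spec$cutoff3]
      if (length(nb) < 2L) next
      for (a in seq_len(length(nb) - 1L)) for (b in (a + 1L):length(nb)) {
        j <- nb[a]; k <- nb[b]
        rij <- d[c_i, j]; rik <- d[c_i, k]; rjk <- d[j, k]
        ci <- (rij^2 + rik^2 - rjk^2) / (2 * rij * rik)
        cj <- (rij^2 + rjk^2 - rik^2) / (2 * rij * rjk)
        ck <- (rik^2 + rjk^2 - rij^2) / (2 * rik * rjk)
        ci <- max(-1, min(1, ci))
        atm <- (1 + 3 * ci * cj * ck) / (rij * rik * rjk)^3
        zp1 <- min(z[j], z[k]); zp2 <- max(z[j], z[k])
        pk <- which(spec$pairs$z1 == zp1 & spec$pairs$z2 == zp2)
        ck_idx <- match(z[c_i], universe)
        bag <- which(spec$trips$center == ck_idx & spec$trips$pair == pk)
        three[, bag] <- three[, bag] + z[c_i] * z[j] * z[k] * atm *
          stats::dnorm(spec$t_grid, acos(ci), spec$sigma3) * spec$dtheta
      }
    }
  }
  stats::setNames(c(one, as.vector(two), as.vector(three)), spec$labels)
}
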