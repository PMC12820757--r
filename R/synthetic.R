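#' Specification for the synthetic data generator
#'
#' Controls the toy-molecule geometry sampler and the calibration of the mock
#' tight-binding records. The two correlation calibrations default to the
#' dipole and dispersion/polarizability Pearson correlations that
#' tight-binding properties show against high-level reference labels on
#' drug-like molecules: `rho_dipole = 0.94` between the mock tight-binding
#' dipole norm and the hidden reference dipole, and `rho_mbd_alpha = -0.61`
#' between the mock many-body dispersion energy and the hidden reference
#' polarizability.
#'
#' @param palette element symbols the toy molecules draw from.
#' @param size_range integer range of atom counts.
#' @param min_dist minimum interatomic distance, Angstrom.
#' @param rho_dipole target Pearson correlation between mock `||mu_TB||` and
#'   the hidden reference dipole, `|rho| < 1`.
#' @param rho_mbd_alpha target Pearson correlation between mock `E_mbd` and
#'   the hidden reference polarizability, `|rho| < 1`.
#' @param noise named list of per-property noise scales (sd) used for the
#'   remaining mock energies.
#' @return object of class `"qd_mockspec"`.
#' @export
mock_spec <- function(palette = c("H", "C", "N", "O"),
                      size_range = c(3L, 8L), min_dist = 0.8,
                      rho_dipole = 0.94, rho_mbd_alpha = -0.61,
                      noise = list(energy = 0.3, charge = 0.12)) {
  stopifnot(min_dist > 0, all(size_range >= 1L),
            abs(rho_dipole) < 1, abs(rho_mbd_alpha) < 1)
  atomic_number(palette)  # validate symbols
  structure(list(palette = palette,
                 size_range = as.integer(sort(size_range)),
                 min_dist = min_dist, rho_dipole = rho_dipole,
                 rho_mbd_alpha = rho_mbd_alpha, noise = noise),
            class = "qd_mockspec")
}

.with_seed <- function(seed, expr) {
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                           globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(seed)
  expr
}

#' Generate toy molecules
#'
#' Random sizes and elements from the palette; coordinates drawn by rejection
#' sampling in a cube scaled with the atom count so that all pairwise
#' distances respect `spec$min_dist`. Deterministic given the seed.
#'
#' @param n number of molecules.
#' @param spec a [mock_spec()].
#' @param seed RNG seed.
#' @return list of [molecule()]s with ids `"syn_1"`, `"syn_2"`, ...
#' @export
gen_toy_molecules <- function(n, spec = mock_spec(), seed = 1L) {
  stopifnot(inherits(spec, "qd_mockspec"), n >= 1L)
  .with_seed(seed, {
    lapply(seq_len(n), function(i) {
      size <- sample(spec$size_range[1]:spec$size_range[2], 1L)
      elements <- sample(spec$palette, size, replace = TRUE)
      box <- max(2.5, 2.2 * size^(1 / 3)) # generous density for rejection
      coords <- matrix(NA_real_, size, 3)
      coords[1, ] <- stats::runif(3, 0, box)
      for (k in seq_len(size)[-1]) {
        placed <- FALSE
        for (try in seq_len(500L)) {
          p <- stats::runif(3, 0, box)
          dists <- sqrt(rowSums(sweep(coords[seq_len(k - 1L), ,
                                             drop = FALSE], 2, p)^2))
          if (all(dists >= spec$min_dist)) {
            coords[k, ] <- p
            placed <- TRUE
            break
          }
        }
        if (!placed)
          stop("generation error: cannot place atom ", k,
               " at the requested density", call. = FALSE)
      }
      molecule(elements, coords, id = paste0("syn_", i))
    })
  })
}

#' Generate mock tight-binding records with calibrated correlations
#'
#' For each molecule, emits an internally consistent [qm_record()] (eigenvalue
#' gap matching `E_gap_TB`, Mulliken charges summing to zero, size-extensive
#' energies) together with hidden "reference" targets (`mu`, `alpha`,
#' `E_gap`, `E_AT`) that play the role of high-level labels. The mock
#' `||mu_TB||` is linear in the hidden reference dipole plus independent
#' Gaussian noise, with the loading chosen so the population Pearson
#' correlation equals `spec$rho_dipole` exactly; `E_mbd` is tied to the
#' hidden polarizability the same way at `spec$rho_mbd_alpha`. Sample
#' correlations therefore converge to the calibrations as `n` grows.
#'
#' @param mols list of [molecule()]s (e.g. from [gen_toy_molecules()]).
#' @param spec a [mock_spec()].
#' @param seed RNG seed.
#' @return list with `records` (named list of [qm_record()]s keyed by
#'   molecule id) and `references` (data frame: `molecule_id`, `mu`, `alpha`,
#'   `E_gap`, `E_AT` with the units eA, Bohr^3, eV, eV).
#' @export
gen_mock_qm <- function(mols, spec = mock_spec(), seed = 1L) {
  stopifnot(inherits(spec, "qd_mockspec"), length(mols) >= 1L)
  nmol <- length(mols)
  e_sd <- spec$noise$energy
  .with_seed(seed, {
    # hidden reference dipole: intensive, mean 2.5 eA, sd 0.6
    mu_ref <- stats::rnorm(nmol, 2.5, 0.6)
    # mock TB dipole norm: linear in mu_ref + independent noise, population
    # Pearson r = rho_dipole by construction (s2 = own sd)
    s1 <- 0.6; s2 <- 0.5
    b <- spec$rho_dipole * s2 / s1
    mu_tb <- 2.0 + b * (mu_ref - 2.5) +
      stats::rnorm(nmol, 0, s2 * sqrt(1 - spec$rho_dipole^2))
    mu_tb <- pmax(mu_tb, 1e-8)  # guard; P(hit) ~ 3e-5, leaves r intact

    n_at <- vapply(mols, n_atoms, integer(1))
    # hidden reference polarizability: extensive in the atom count
    alpha_ref <- 2 + 1.2 * n_at + stats::rnorm(nmol, 0, 1.0)
    lo <- spec$size_range[1]; hi <- spec$size_range[2]
    var_n <- ((hi - lo + 1)^2 - 1) / 12
    s_alpha <- sqrt(1.2^2 * var_n + 1.0^2)
    s_e <- 0.4
    b2 <- spec$rho_mbd_alpha * s_e / s_alpha
    mean_alpha <- 2 + 1.2 * (lo + hi) / 2
    e_mbd <- -1.5 + b2 * (alpha_ref - mean_alpha) +
      stats::rnorm(nmol, 0, s_e * sqrt(1 - spec$rho_mbd_alpha^2))

    records <- vector("list", nmol)
    gap_tb <- numeric(nmol)
    for (i in seq_len(nmol)) {
      m <- mols[[i]]
      ne <- sum(m$Z)
      n_occ <- max(4L, as.integer(floor(ne / 2)))
      n_virt <- 6L
      homo <- stats::rnorm(1, -6, 0.5)
      gap_tb[i] <- stats::runif(1, 1.0, 8.0)
      occ <- homo - rev(cumsum(stats::runif(n_occ - 1L, 0.2, 1.5)))
      lumo <- homo + gap_tb[i]
      virt <- lumo + c(0, cumsum(stats::runif(n_virt - 1L, 0.2, 1.5)))
      mo <- c(occ, homo, virt)
      q <- stats::rnorm(length(m$Z), 0, spec$noise$charge)
      q <- q - mean(q)
      dir <- stats::rnorm(3)
      dir <- dir / sqrt(sum(dir^2))
      nn <- n_at[i]
      records[[i]] <- qm_record(
        E_Fermi = homo + gap_tb[i] / 2,
        E_band = 2 * sum(c(occ, homo)),
        NE = ne,
        E_H0 = -25 * nn + stats::rnorm(1, 0, e_sd),
        E_scc = -0.05 * nn + stats::rnorm(1, 0, e_sd / 3),
        E_3rd = -0.02 * nn + stats::rnorm(1, 0, e_sd / 10),
        E_rep = 0.3 * nn + abs(stats::rnorm(1, 0, e_sd)),
        E_mbd = e_mbd[i],
        mu_TB_vec = dir * mu_tb[i],
        mo_energies = mo,
        homo_index = n_occ,
        mulliken = q)
    }
    names(records) <- vapply(mols, function(m) m$id, character(1))
    references <- data.frame(
      molecule_id = names(records),
      mu = mu_ref,
      alpha = alpha_ref,
      E_gap = 1.1 * gap_tb + stats::rnorm(nmol, 0, 0.8),
      E_AT = -2.0 * n_at + stats::rnorm(nmol, 0, 0.5),
      stringsAsFactors = FALSE)
    list(records = records, references = references)
  })
}

#' Generate synthetic regression targets from a descriptor block
#'
#' Targets come from a disclosed generative model so recovery tests can
#' quantify estimation error exactly:
#' \describe{
#'   \item{linear}{a linear function of a few randomly chosen (z-scored)
#'     columns, noise-free;}
#'   \item{linear_noise}{the same plus additive Gaussian noise `noise_sd`;}
#'   \item{mix}{signal drawn from a geometric and an electronic column subset
#'     (identified by label prefix) with weights `geometry_weight` and
#'     `electronic_weight`, plus optional noise.}
#' }
#'
#' @param block a [descriptor_block()] (for `"mix"`, a [concat_blocks()]
#'   result whose labels carry block-name prefixes).
#' @param kind `"linear"`, `"linear_noise"` or `"mix"`.
#' @param seed RNG seed.
#' @param noise_sd noise standard deviation (`linear_noise`, `mix`).
#' @param n_signal number of signal columns per subset.
#' @param geometry_prefix,electronic_prefix label prefixes locating the two
#'   subsets for `"mix"` (defaults `"SLATM."`/`"BOB."` and `"DQM."`).
#' @param geometry_weight,electronic_weight subset weights for `"mix"`.
#' @return list with `y`, `coefficients` (named by column label), and
#'   `noise_sd`.
#' @export
gen_targets <- function(block, kind = c("linear", "linear_noise", "mix"),
                        seed = 1L, noise_sd = 0.1, n_signal = 5L,
                        geometry_prefix = c("SLATM.", "BOB."),
                        electronic_prefix = "DQM.",
                        geometry_weight = 1, electronic_weight = 1) {
  kind <- match.arg(kind)
  stopifnot(inherits(block, "qd_block"))
  m <- block$matrix
  # z-score columns internally so coefficients act on comparable scales
  mu <- colMeans(m)
  sd_ <- sqrt(pmax(colMeans(sweep(m, 2, mu)^2), 0))
  active <- which(sd_ > 1e-12)
  zc <- sweep(sweep(m[, active, drop = FALSE], 2, mu[active]), 2,
              sd_[active], "/")
  .with_seed(seed, {
    pick <- function(cols, k) {
      cols <- intersect(cols, seq_along(active))
      if (!length(cols)) stop("no usable signal columns", call. = FALSE)
      sample(cols, min(k, length(cols)))
    }
    beta <- numeric(ncol(zc))
    if (kind == "mix") {
      labs <- block$labels[active]
      geo <- which(Reduce(`|`, lapply(geometry_prefix, startsWith,
                                      x = labs)))
      ele <- which(startsWith(labs, electronic_prefix))
      if (!length(geo) || !length(ele))
        stop("mix targets need both a geometric and an electronic subset",
             call. = FALSE)
      gsel <- pick(geo, n_signal)
      esel <- pick(ele, n_signal)
      beta[gsel] <- geometry_weight * stats::rnorm(length(gsel))
      beta[esel] <- electronic_weight * stats::rnorm(length(esel))
    } else {
      sel <- pick(seq_along(active), n_signal)
      beta[sel] <- stats::rnorm(length(sel))
    }
    y <- drop(zc %*% beta)
    if (kind %in% c("linear_noise", "mix") && noise_sd > 0)
      y <- y + stats::rnorm(nrow(zc), 0, noise_sd)
    coefficients <- stats::setNames(beta, block$labels[active])
    list(y = y, coefficients = coefficients,
         noise_sd = if (kind == "linear") 0 else noise_sd)
  })
}
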