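#' Statistical-coil ensemble generation
#'
#' A desk-scale statistical-coil sampler for disordered chains: per-residue
#' backbone dihedrals are drawn from a four-basin Gaussian mixture (beta,
#' PPII, alpha-R, alpha-L; glycine widened, proline phi-pinned), backbones
#' are built with ideal trans-peptide geometry, and conformers with
#' long-range C-alpha clashes are rejected and resampled. Default basin
#' weights are calibrated so 200-residue ensembles show Flory-like radius
#' of gyration statistics.
#'
#' @name ensemble_sample
NULL

#' Dihedral basin definitions and weights for the coil sampler
#'
#' @param weights mixture weights over the basins `beta`, `ppii`, `alphaR`,
#'   `alphaL` for generic residues (normalized internally).
#' @param gly_weights,pro_weights overrides for glycine (widened, more
#'   alpha-L) and proline (phi pinned near -65, PPII-dominated).
#' @param sd_scale multiplies all basin standard deviations.
#' @return list describing the mixture; see source for basin centers.
#' @export
coil_basins <- function(weights = c(beta = 0.32, ppii = 0.42,
                                    alphaR = 0.21, alphaL = 0.05),
                        gly_weights = c(beta = 0.25, ppii = 0.25,
                                        alphaR = 0.20, alphaL = 0.30),
                        pro_weights = c(beta = 0.0, ppii = 0.85,
                                        alphaR = 0.15, alphaL = 0.0),
                        sd_scale = 1) {
  centers <- rbind(beta  = c(phi = -120, psi = 135),
                   ppii  = c(phi = -75,  psi = 145),
                   alphaR = c(phi = -63, psi = -43),
                   alphaL = c(phi = 57,  psi = 42))
  sds <- rbind(beta  = c(phi = 25, psi = 20),
               ppii  = c(phi = 15, psi = 15),
               alphaR = c(phi = 10, psi = 11),
               alphaL = c(phi = 12, psi = 12)) * sd_scale
  list(centers = centers, sds = sds,
       weights = weights / sum(weights),
       gly_weights = gly_weights / sum(gly_weights),
       pro_weights = pro_weights / sum(pro_weights),
       gly_sd_scale = 1.8, pro_phi = c(mean = -65, sd = 6))
}

#' Helical-basin dihedral bounds
#'
#' A residue is flagged helical when phi is in `phi_bounds` and psi in
#' `psi_bounds` (degrees).
#' @param phi_bounds,psi_bounds numeric length-2 vectors.
#' @return list with the two bounds.
#' @export
helical_basin <- function(phi_bounds = c(-90, -30), psi_bounds = c(-77, -17)) {
  list(phi = phi_bounds, psi = psi_bounds)
}

BASIN_NAMES <- c("beta", "ppii", "alphaR", "alphaL")

# sample dihedral matrices for one conformer; returns list(phi, psi, basin)
.sample_dihedrals <- function(res, basins) {
  n <- length(res)
  basin <- integer(n)
  phi <- psi <- numeric(n)
  for (i in seq_len(n)) {
    w <- if (res[i] == "G") basins$gly_weights
         else if (res[i] == "P") basins$pro_weights
         else basins$weights
    b <- sample.int(4L, 1L, prob = w)
    basin[i] <- b
    ssc <- if (res[i] == "G") basins$gly_sd_scale else 1
    phi[i] <- stats::rnorm(1, basins$centers[b, 1], basins$sds[b, 1] * ssc)
    psi[i] <- stats::rnorm(1, basins$centers[b, 2], basins$sds[b, 2] * ssc)
    if (res[i] == "P")
      phi[i] <- stats::rnorm(1, basins$pro_phi[["mean"]], basins$pro_phi[["sd"]])
  }
  list(phi = phi, psi = psi, basin = basin)
}

# ideal trans-peptide geometry (Angstrom, degrees)
BB_GEOM <- list(b_NCA = 1.458, b_CAC = 1.525, b_CN = 1.329,
                a_NCAC = 111.2, a_CACN = 116.2, a_CNCA = 121.7)

# place atom D given A,B,C with bond |CD|, angle B-C-D, torsion A-B-C-D
.place_atom <- function(a, b, c2, bond, theta_rad, tau_rad) {
  bc <- c2 - b
  bc <- bc / sqrt(sum(bc * bc))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n * n))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  st <- sin(theta_rad)
  c2 + bond * (-cos(theta_rad) * bc + st * cos(tau_rad) * m +
                 st * sin(tau_rad) * n)
}

#' Build N, CA, C backbone coordinates from dihedral angles
#'
#' Ideal bond lengths/angles, omega fixed at 180 degrees (trans). phi of
#' the first residue and psi of the last are not used.
#'
#' @param phi,psi per-residue dihedrals in degrees.
#' @return numeric matrix (3*n x 3); rows ordered N, CA, C per residue.
#' @export
build_backbone <- function(phi, psi) {
  n <- length(phi)
  stopifnot(length(psi) == n, n >= 1L)
  g <- BB_GEOM
  d2r <- pi / 180
  xyz <- matrix(0, nrow = 3L * n, ncol = 3L)
  xyz[2, ] <- c(g$b_NCA, 0, 0)
  ang <- g$a_NCAC * d2r
  xyz[3, ] <- xyz[2, ] + g$b_CAC * c(-cos(ang), sin(ang), 0)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      r0 <- 3L * (i - 1L)
      Ni <- xyz[r0 + 1L, ]; CAi <- xyz[r0 + 2L, ]; Ci <- xyz[r0 + 3L, ]
      Nn <- .place_atom(Ni, CAi, Ci, g$b_CN, g$a_CACN * d2r, psi[i] * d2r)
      CAn <- .place_atom(CAi, Ci, Nn, g$b_NCA, g$a_CNCA * d2r, pi)
      Cn <- .place_atom(Ci, Nn, CAn, g$b_CAC, g$a_NCAC * d2r, phi[i + 1L] * d2r)
      xyz[r0 + 4L, ] <- Nn
      xyz[r0 + 5L, ] <- CAn
      xyz[r0 + 6L, ] <- Cn
    }
  }
  xyz
}

# CA coordinate rows of a backbone matrix
.ca_coords <- function(xyz) xyz[seq(2L, nrow(xyz), by = 3L), , drop = FALSE]

# TRUE when any CA pair with |i-j| >= min_sep is closer than cutoff
.has_clash <- function(ca, cutoff = 4.0, min_sep = 3L) {
  n <- nrow(ca)
  if (n < min_sep + 1L) return(FALSE)
  dm <- as.matrix(stats::dist(ca))
  idx <- abs(row(dm) - col(dm)) >= min_sep
  any(dm[idx] < cutoff)
}

# grow one chain residue by residue with local clash-driven redraws;
# returns NULL when a position cannot be placed within local_tries
.grow_chain <- function(res, draw_res, cutoff, min_sep, local_tries) {
  g <- BB_GEOM
  d2r <- pi / 180
  L <- length(res)
  phi <- psi <- numeric(L)
  basin <- integer(L)
  xyz <- matrix(0, 3L * L, 3L)
  ca <- matrix(0, L, 3L)
  d <- draw_res(1L)
  basin[1] <- d[1]; phi[1] <- d[2]; psi[1] <- d[3]
  xyz[2, ] <- c(g$b_NCA, 0, 0)
  ang <- g$a_NCAC * d2r
  xyz[3, ] <- xyz[2, ] + g$b_CAC * c(-cos(ang), sin(ang), 0)
  ca[1, ] <- xyz[2, ]
  cut2 <- cutoff^2
  for (i in seq_len(L - 1L)) {
    d <- draw_res(i + 1L)
    r0 <- 3L * (i - 1L)
    tries <- 0L
    repeat {
      Nn <- .place_atom(xyz[r0 + 1L, ], xyz[r0 + 2L, ], xyz[r0 + 3L, ],
                        g$b_CN, g$a_CACN * d2r, psi[i] * d2r)
      CAn <- .place_atom(xyz[r0 + 2L, ], xyz[r0 + 3L, ], Nn,
                         g$b_NCA, g$a_CNCA * d2r, pi)
      jmax <- i + 1L - min_sep
      clash <- FALSE
      if (jmax >= 1L) {
        prev <- ca[seq_len(jmax), , drop = FALSE]
        dd <- (prev[, 1] - CAn[1])^2 + (prev[, 2] - CAn[2])^2 +
              (prev[, 3] - CAn[3])^2
        clash <- any(dd < cut2)
      }
      if (!clash) break
      tries <- tries + 1L
      if (tries > local_tries) return(NULL)
      # redraw the preceding residue's dihedrals; its CA stays fixed
      dprev <- draw_res(i)
      basin[i] <- dprev[1]; phi[i] <- dprev[2]; psi[i] <- dprev[3]
      if (i >= 2L)
        xyz[r0 + 3L, ] <- .place_atom(xyz[r0 - 3L + 3L, ], xyz[r0 + 1L, ],
                                      xyz[r0 + 2L, ], g$b_CAC,
                                      g$a_NCAC * d2r, phi[i] * d2r)
    }
    basin[i + 1L] <- d[1]; phi[i + 1L] <- d[2]; psi[i + 1L] <- d[3]
    xyz[r0 + 4L, ] <- Nn
    xyz[r0 + 5L, ] <- CAn
    xyz[r0 + 6L, ] <- .place_atom(xyz[r0 + 3L, ], Nn, CAn, g$b_CAC,
                                  g$a_NCAC * d2r, phi[i + 1L] * d2r)
    ca[i + 1L, ] <- CAn
  }
  list(phi = phi, psi = psi, basin = basin, xyz = xyz, ca = ca)
}

#' Radius of gyration of a conformer
#'
#' Root-mean-square distance of the C-alpha atoms from their centroid;
#' invariant under rigid motions.
#'
#' @param x a conformer (list with `coords`) or a coordinate matrix. A
#'   matrix with 3 rows per residue is interpreted as an N/CA/C backbone
#'   and reduced to C-alphas when `ca_only = TRUE`.
#' @param ca_only reduce a full backbone matrix to C-alphas (default TRUE).
#' @return Rg in Angstrom.
#' @export
radius_of_gyration <- function(x, ca_only = TRUE) {
  m <- if (is.list(x) && !is.null(x$coords)) x$coords else x
  stopifnot(is.matrix(m), nrow(m) >= 1L)
  if (ca_only && nrow(m) %% 3L == 0L && nrow(m) > 3L) m <- .ca_coords(m)
  ctr <- colMeans(m)
  sqrt(mean(rowSums((m - matrix(ctr, nrow(m), 3, byrow = TRUE))^2)))
}

#' Sample a statistical-coil ensemble
#'
#' @param sequence residue string, or an integer chain length (then a
#'   generic non-Gly/Pro composition is assumed).
#' @param n number of conformers.
#' @param seed RNG seed (required for reproducibility).
#' @param basins [coil_basins()].
#' @param basin_bounds [helical_basin()] bounds used for the helical flag.
#' @param build_coords build backbones and apply clash rejection (default
#'   TRUE). Shift-only workflows can skip coordinates for speed; no clash
#'   screen is applied then.
#' @param clash_cutoff C-alpha clash distance, Angstrom, for pairs at least
#'   `min_sep` residues apart. The chain is grown residue by residue; a
#'   clashing placement redraws the local dihedrals (up to `local_tries`)
#'   and the whole chain restarts when a position is irrecoverable.
#' @param min_sep minimal sequence separation for the clash screen.
#' @param local_tries per-residue redraw cap before a chain restart.
#' @param max_attempts whole-chain restart cap per conformer before
#'   erroring.
#' @param weight_profile optional n_res x 4 matrix of per-residue basin
#'   weights overriding the residue-type weights (used by the iterative
#'   selection scheme to bias pools toward a selected ensemble).
#' @return an `ensemble_pool`: list with `sequence`, `phi`/`psi` (n x L
#'   matrices), `basin` (n x L integer matrix), `flags` (n x L logical,
#'   helical basin), `rg` (length n, NA without coordinates), `conformers`
#'   (list of per-conformer coordinate matrices, NULL without coordinates).
#' @export
sample_coil_ensemble <- function(sequence, n, seed = NULL,
                                 basins = coil_basins(),
                                 basin_bounds = helical_basin(),
                                 build_coords = TRUE, clash_cutoff = 4.0,
                                 min_sep = 3L, local_tries = 40L,
                                 max_attempts = 50L,
                                 weight_profile = NULL) {
  stopifnot(n >= 1L)
  if (!is.null(seed)) set.seed(seed)
  res <- if (is.character(sequence)) strsplit(toupper(sequence), "")[[1]]
         else rep("A", as.integer(sequence))
  L <- length(res)
  phi <- psi <- matrix(0, n, L)
  basin <- matrix(0L, n, L)
  rg <- rep(NA_real_, n)
  coords <- if (build_coords) vector("list", n) else NULL
  draw_res <- function(i) {
    if (is.null(weight_profile)) {
      w <- if (res[i] == "G") basins$gly_weights
           else if (res[i] == "P") basins$pro_weights
           else basins$weights
      ssc <- if (res[i] == "G") basins$gly_sd_scale else 1
    } else {
      w <- weight_profile[i, ]
      ssc <- 1
    }
    b <- sample.int(4L, 1L, prob = w)
    ph <- stats::rnorm(1, basins$centers[b, 1], basins$sds[b, 1] * ssc)
    ps <- stats::rnorm(1, basins$centers[b, 2], basins$sds[b, 2] * ssc)
    if (res[i] == "P")
      ph <- stats::rnorm(1, basins$pro_phi[["mean"]], basins$pro_phi[["sd"]])
    c(b, ph, ps)
  }
  for (k in seq_len(n)) {
    if (!build_coords) {
      d <- vapply(seq_len(L), draw_res, numeric(3))
      basin[k, ] <- as.integer(d[1, ]); phi[k, ] <- d[2, ]; psi[k, ] <- d[3, ]
      next
    }
    done <- FALSE
    for (att in seq_len(max_attempts)) {
      grown <- .grow_chain(res, draw_res, clash_cutoff, min_sep, local_tries)
      if (!is.null(grown)) { done <- TRUE; break }
    }
    if (!done) stop("clash-rejection cap exceeded (", max_attempts,
                    " chain restarts); relax clash_cutoff or basin widths")
    phi[k, ] <- grown$phi
    psi[k, ] <- grown$psi
    basin[k, ] <- grown$basin
    coords[[k]] <- grown$xyz
    rg[k] <- radius_of_gyration(grown$ca, ca_only = FALSE)
  }
  flags <- phi >= basin_bounds$phi[1] & phi <= basin_bounds$phi[2] &
           psi >= basin_bounds$psi[1] & psi <= basin_bounds$psi[2]
  structure(list(sequence = paste(res, collapse = ""), phi = phi, psi = psi,
                 basin = basin, flags = flags, rg = rg, conformers = coords,
                 basins = basins, basin_bounds = basin_bounds),
            class = "ensemble_pool")
}

#' @export
print.ensemble_pool <- function(x, ...) {
  cat(sprintf("<ensemble_pool> %d conformers x %d residues%s\n",
              nrow(x$phi), ncol(x$phi),
              if (all(is.na(x$rg))) "" else
                sprintf(", mean Rg %.1f A", mean(x$rg, na.rm = TRUE))))
  invisible(x)
}

#' Per-residue helical propensity of a pool or sub-ensemble
#'
#' Fraction of conformers whose dihedrals fall in the helical basin at each
#' residue.
#'
#' @param pool `ensemble_pool`.
#' @param indices optional conformer indices (multiset allowed); default all.
#' @return numeric vector of length n_res in [0,1].
#' @export
ensemble_propensity <- function(pool, indices = NULL) {
  f <- pool$flags
  if (!is.null(indices)) f <- f[indices, , drop = FALSE]
  colMeans(f)
}

#' Per-residue basin frequencies of a pool or sub-ensemble
#'
#' @param pool `ensemble_pool`.
#' @param indices optional conformer indices.
#' @return n_res x 4 matrix (columns beta, ppii, alphaR, alphaL), rows
#'   summing to 1.
#' @export
basin_frequencies <- function(pool, indices = NULL) {
  b <- pool$basin
  if (!is.null(indices)) b <- b[indices, , drop = FALSE]
  out <- sapply(1:4, function(k) colMeans(b == k))
  colnames(out) <- BASIN_NAMES
  out
}
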