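## Quasi-static complex-potential finite-element solver. The single material
## coefficient is the complex conductivity sigma = j*w*eps0*eps_eff; the weak
## form of div(sigma grad phi) = 0 enforces continuity of the normal current
## density across tissue interfaces naturally. The complex symmetric system is
## solved as an equivalent 2N real sparse system (Matrix / CSparse LU).

#' Material map for a knee mesh
#'
#' Returns a function `(region, frequency) -> complex conductivity` for the
#' five mesh regions. Muscle is anisotropic: the in-plane (transverse to the
#' fibers, which run along the limb axis) component comes from the
#' transversal row, the axial component from the parallel row. All other
#' tissues are isotropic.
#'
#' @param tissue_table A tissue table.
#' @param anisotropic_muscle Use the parallel row for the axial muscle
#'   component (default); if FALSE muscle is isotropic transversal.
#' @return A function usable as the `materials` argument of the solver; each
#'   call returns `c(t = , z = )` complex conductivities in S/m (equal for
#'   isotropic tissues).
#' @export
knee_materials <- function(tissue_table = default_tissue_table(),
                           anisotropic_muscle = TRUE) {
  validate_tissue_table(tissue_table)
  map <- c(bone = "Bone", muscle = "Muscle (Transversal)", fat = "Fat",
           wet_skin = "Wet Skin", dry_skin = "Dry Skin")
  function(region, frequency) {
    st <- complex_conductivity(tissue_table[[map[[region]]]], frequency)
    sz <- if (region == "muscle" && anisotropic_muscle)
      complex_conductivity(tissue_table[["Muscle (Parallel)"]], frequency)
    else st
    c(t = st, z = sz)
  }
}

#' Uniform material map
#'
#' A single (possibly complex, possibly anisotropic) conductivity for every
#' region; mainly for analytic solver tests.
#'
#' @param sigma_t In-plane complex conductivity in S/m.
#' @param sigma_z Axial complex conductivity (defaults to `sigma_t`).
#' @return A materials function.
#' @export
uniform_materials <- function(sigma_t, sigma_z = sigma_t) {
  force(sigma_t); force(sigma_z)
  function(region, frequency) c(t = as.complex(sigma_t), z = as.complex(sigma_z))
}

element_coefficients <- function(mesh, materials, frequency) {
  rn <- mesh$region_names
  per <- lapply(rn, function(r) {
    s <- materials(r, frequency)
    if (length(s) == 1L) s <- c(t = s, z = s)
    as.complex(s)
  })
  st <- vapply(per, function(s) s[[1L]], complex(1))[mesh$region]
  sz <- vapply(per, function(s) s[[2L]], complex(1))[mesh$region]
  list(t = st, z = sz)
}

## Complex stiffness triplets in node indexing.
assemble_triplets <- function(mesh, materials, frequency) {
  k <- mesh$geom$nloc
  coef <- element_coefficients(mesh, materials, frequency)
  vals <- coef$t * mesh$geom$Gt
  if (!is.null(mesh$geom$Gz)) vals <- vals + coef$z * mesh$geom$Gz
  list(i = as.vector(mesh$elems[, rep(seq_len(k), times = k)]),
       j = as.vector(mesh$elems[, rep(seq_len(k), each = k)]),
       x = as.vector(vals))
}

#' Boundary specification for the potential problem
#'
#' Terminal patches carry prescribed (Dirichlet) potentials; floating patches
#' are ideal equipotential electrodes drawing zero net current; the rest of
#' the skin surface is insulated (natural boundary condition), and no external
#' current density is applied.
#'
#' @param terminals List of `list(nodes = <node indices>, value = <complex potential>)`.
#' @param floating List of node-index vectors (each an equipotential patch).
#' @return An object of class `"boundary_spec"`.
#' @export
boundary_spec <- function(terminals, floating = list()) {
  if (!length(terminals))
    stop_validation("at least one terminal is required (the all-Neumann problem is singular)")
  for (t in terminals) {
    if (!length(t$nodes)) stop_validation("terminal with empty node set")
    if (!is.finite(Re(t$value)) || !is.finite(Im(as.complex(t$value))))
      stop_validation("terminal potentials must be finite")
  }
  all_sets <- c(lapply(terminals, `[[`, "nodes"), floating)
  if (length(all_sets) > 1) {
    pairs <- utils::combn(length(all_sets), 2)
    for (q in seq_len(ncol(pairs)))
      if (length(intersect(all_sets[[pairs[1, q]]], all_sets[[pairs[2, q]]])))
        stop_validation("terminal/floating patches must be disjoint")
  }
  structure(list(terminals = terminals, floating = floating),
            class = "boundary_spec")
}

## Merge each patch into a single DOF (equipotential electrode); returns the
## node -> dof map and the dof index of each patch.
merge_dofs <- function(n_nodes, patches) {
  rep_node <- seq_len(n_nodes)
  for (nodes in patches) rep_node[nodes] <- min(nodes)
  uid <- unique(rep_node)
  dof <- match(rep_node, uid)
  list(dof = dof, ndof = length(uid),
       patch_dof = vapply(patches, function(nodes) dof[min(nodes)], integer(1)))
}

## Solve the reduced complex symmetric system K_ff u = -K_fc u_c.
##
## K = Kr + i*Ki with Kr (conduction losses) and Ki (displacement) both
## positive semidefinite, so M = Kr + Ki is SPD and a single CHOLMOD
## factorization preconditions the whole system: the eigenvalues of
## M^{-1} K lie on the arc (1 + it)/(1 + t), t >= 0, bounded away from the
## origin, and plain (unrestarted) GMRES converges in a few tens of
## iterations for any passive tissue table. Falls back to a direct solve on
## the equivalent 2N real system if the factorization or iteration fails.
solve_complex_sparse <- function(Kr, Ki, free, fixed, u_fixed,
                                 tol = 1e-11, maxiter = 200L) {
  Krf <- Kr[free, free, drop = FALSE]
  Kif <- Ki[free, free, drop = FALSE]
  rhs_re <- as.vector(Kr[free, fixed, drop = FALSE] %*% Re(u_fixed) -
                        Ki[free, fixed, drop = FALSE] %*% Im(u_fixed))
  rhs_im <- as.vector(Ki[free, fixed, drop = FALSE] %*% Re(u_fixed) +
                        Kr[free, fixed, drop = FALSE] %*% Im(u_fixed))
  b <- complex(real = -rhs_re, imaginary = -rhs_im)
  matvec <- function(x) {
    xr <- Re(x); xi <- Im(x)
    complex(real = as.vector(Krf %*% xr) - as.vector(Kif %*% xi),
            imaginary = as.vector(Kif %*% xr) + as.vector(Krf %*% xi))
  }
  direct <- function() {
    A <- rbind(cbind(Krf, -Kif), cbind(Kif, Krf))
    sol <- Matrix::solve(A, c(Re(b), Im(b)))
    nf <- length(free)
    complex(real = sol[seq_len(nf)], imaginary = sol[nf + seq_len(nf)])
  }
  ch <- tryCatch(Matrix::Cholesky(Matrix::forceSymmetric(Krf + Kif)),
                 error = function(e) NULL)
  if (is.null(ch)) return(direct())
  prec <- function(x)
    complex(real = as.vector(Matrix::solve(ch, Re(x))),
            imaginary = as.vector(Matrix::solve(ch, Im(x))))
  bt <- prec(b)
  bnorm <- sqrt(Re(sum(Conj(bt) * bt)))
  if (bnorm == 0) return(complex(length.out = length(free)))
  ## unrestarted GMRES on the preconditioned system
  V <- matrix(0i, length(free), maxiter + 1L)
  H <- matrix(0i, maxiter + 1L, maxiter)
  V[, 1L] <- bt / bnorm
  beta <- c(bnorm, rep(0i, maxiter))
  y <- NULL
  for (k in seq_len(maxiter)) {
    w <- prec(matvec(V[, k]))
    for (j in seq_len(k)) {           # modified Gram-Schmidt
      H[j, k] <- sum(Conj(V[, j]) * w)
      w <- w - H[j, k] * V[, j]
    }
    H[k + 1L, k] <- sqrt(Re(sum(Conj(w) * w)))
    Hk <- H[seq_len(k + 1L), seq_len(k), drop = FALSE]
    y <- qr.solve(Hk, beta[seq_len(k + 1L)])
    res <- sqrt(sum(Mod(Hk %*% y - beta[seq_len(k + 1L)])^2)) / bnorm
    if (res <= tol || Mod(H[k + 1L, k]) < 1e-300) {
      return(V[, seq_len(k), drop = FALSE] %*% y |> as.vector())
    }
    V[, k + 1L] <- w / H[k + 1L, k]
  }
  warning("iterative solver did not reach tolerance; using direct solve")
  direct()
}

#' Solve the complex-potential problem at one frequency
#'
#' Discrete weak solution of `div(sigma grad phi) = 0` on the meshed domain
#' with the given material coefficients and boundary specification.
#'
#' @param mesh A [knee_mesh()].
#' @param materials A materials function (see [knee_materials()]).
#' @param boundary A [boundary_spec()].
#' @param frequency Frequency in Hz.
#' @return An object of class `"potential_field"`: complex nodal potentials
#'   `u`, the merged-DOF solution and system, and per-terminal currents.
#' @export
solve_potential <- function(mesh, materials, boundary, frequency) {
  if (!inherits(mesh, "knee_mesh")) stop_validation("'mesh' must be a knee_mesh")
  if (!inherits(boundary, "boundary_spec"))
    stop_validation("'boundary' must be a boundary_spec")
  check_frequency(frequency)
  n <- nrow(mesh$p)
  patches <- c(lapply(boundary$terminals, `[[`, "nodes"), boundary$floating)
  md <- merge_dofs(n, patches)
  nt <- length(boundary$terminals)
  fixed <- md$patch_dof[seq_len(nt)]
  u_fixed <- as.complex(vapply(boundary$terminals, function(t) as.complex(t$value),
                               complex(1)))
  trip <- assemble_triplets(mesh, materials, frequency)
  i <- md$dof[trip$i]; j <- md$dof[trip$j]
  Kr <- Matrix::sparseMatrix(i = i, j = j, x = Re(trip$x),
                             dims = c(md$ndof, md$ndof))
  Ki <- Matrix::sparseMatrix(i = i, j = j, x = Im(trip$x),
                             dims = c(md$ndof, md$ndof))
  free <- setdiff(seq_len(md$ndof), fixed)
  u_dof <- complex(length.out = md$ndof)
  u_dof[fixed] <- u_fixed
  u_dof[free] <- solve_complex_sparse(Kr, Ki, free, fixed, u_fixed)
  Ku <- as.vector(Kr %*% Re(u_dof) - Ki %*% Im(u_dof)) +
    1i * as.vector(Ki %*% Re(u_dof) + Kr %*% Im(u_dof))
  structure(list(u = u_dof[md$dof], u_dof = u_dof, dof = md$dof,
                 patch_dof = md$patch_dof, n_terminals = nt,
                 terminal_current = Ku[fixed], frequency = frequency,
                 residual = Ku, mesh = mesh), class = "potential_field")
}

#' Net current through a terminal patch
#'
#' The discretely consistent flux `integral(sigma grad phi . n dS)` over the
#' patch: the algebraic residual of the merged electrode DOF, positive into
#' the domain. Currents over all terminals of a solved problem sum to zero
#' (discrete charge conservation).
#'
#' @param field A solved [solve_potential()] field.
#' @param patch Terminal index (in the order given to [boundary_spec()]).
#' @return Complex current in A (3D) or A/m (2D per-unit-length).
#' @export
terminal_current <- function(field, patch) {
  if (!inherits(field, "potential_field"))
    stop_validation("'field' must be a potential_field")
  if (patch < 1 || patch > field$n_terminals)
    stop_validation("'patch' is not a terminal of the solved problem")
  field$terminal_current[[patch]]
}

## Volume-integral power: sum over elements of sigma |grad phi|^2, an
## independent cross-check of the terminal currents (test oracle).
element_power <- function(mesh, field, materials, frequency) {
  coef <- element_coefficients(mesh, materials, frequency)
  g <- mesh$geom
  k <- g$nloc
  uloc <- matrix(field$u[mesh$elems], ncol = k)
  gradx <- rowSums(g$gx * uloc); grady <- rowSums(g$gy * uloc)
  tsq <- Mod(gradx)^2 + Mod(grady)^2
  p <- coef$t * tsq * g$measure
  if (!is.null(g$gz)) {
    gradz <- rowSums(g$gz * uloc)
    p <- p + coef$z * Mod(gradz)^2 * g$measure
  }
  sum(p)
}

#' Tetrapolar (or bipolar) transfer impedance at one frequency
#'
#' The drive pair is held at `+V/2` and `-V/2` (ideal equipotential
#' electrodes); the sense pair floats, drawing zero net current, and reads
#' the potential of its patch. `Z = (phi_sense+ - phi_sense-) / I_drive`.
#' When the sense patches coincide with the drive patches (or with
#' `bipolar = TRUE`) the two-electrode impedance `V / I` is returned.
#'
#' In 2D cross-sectional mode the per-unit-length impedance is divided by the
#' electrode height, giving an approximate Ohm reading.
#'
#' @param mesh A [knee_mesh()] built with electrodes.
#' @param materials A materials function.
#' @param frequency Frequency in Hz (scalar).
#' @param drive_v Drive amplitude in V.
#' @param bipolar Return the two-electrode impedance of the drive pair.
#' @return Complex impedance in Ohm.
#' @export
tetrapolar_impedance <- function(mesh, materials, frequency, drive_v = 1,
                                 bipolar = FALSE) {
  if (is.null(mesh$patches))
    stop_validation("mesh was built without electrodes")
  p <- mesh$patches
  degenerate <- setequal(p[[3]], p[[1]]) && setequal(p[[4]], p[[2]])
  terminals <- list(list(nodes = p[[1]], value = drive_v / 2),
                    list(nodes = p[[2]], value = -drive_v / 2))
  floating <- if (degenerate) list() else list(p[[3]], p[[4]])
  bnd <- boundary_spec(terminals, floating)
  field <- solve_potential(mesh, materials, bnd, frequency)
  i_drive <- terminal_current(field, 1)
  z <- if (bipolar || degenerate) drive_v / i_drive
  else {
    vs <- field$u_dof[field$patch_dof[3:4]]
    (vs[1] - vs[2]) / i_drive
  }
  if (mesh$mode == "2d") z <- z / (mesh$electrodes$height_mm * 1e-3)
  z
}

#' Simulated tetrapolar impedance spectrum
#'
#' Re-evaluates the tissue dielectric coefficients and solves the potential
#' problem at each frequency.
#'
#' @param mesh A [knee_mesh()] built with electrodes.
#' @param materials A materials function.
#' @param frequencies Strictly increasing frequencies in Hz (default: the
#'   13-point measurement grid).
#' @param ... Passed to [tetrapolar_impedance()].
#' @return An [impedance_spectrum()].
#' @export
fem_impedance_spectrum <- function(mesh, materials,
                                   frequencies = default_frequencies(), ...) {
  check_frequency(frequencies)
  if (is.unsorted(frequencies, strictly = TRUE))
    stop_validation("frequencies must be strictly increasing")
  z <- vapply(frequencies, function(f) {
    tryCatch(tetrapolar_impedance(mesh, materials, f, ...),
             error = function(e) stop_validation(sprintf(
               "forward solve failed at %g Hz: %s", f, conditionMessage(e))))
  }, complex(1))
  impedance_spectrum(frequencies, z,
                     metadata = list(forward = paste0("fem-", mesh$mode),
                                     resolution = mesh$resolution))
}
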