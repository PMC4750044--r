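#' Oxygen transport model configuration
#'
#' Transient 2D convection-diffusion model of oxygen in a cross-section of
#' the device: a gas-filled serpentine channel (unrolled to its stretched-out
#' length) below a PDMS slab. Oxygen advects with the fully developed laminar
#' flow in the gas layer, diffuses in both layers, partitions at the
#' gas/PDMS interface, and exchanges with the ambient through the outer PDMS
#' surfaces. All concentrations are in percent oxygen, as displayed by the
#' device model.
#'
#' @param channel_length_m unrolled serpentine length: 0.040 m (small array)
#'   or 0.550 m (large array).
#' @param pdms_thickness_m PDMS slab thickness (5 mm).
#' @param channel_height_m gas channel height (500 um).
#' @param D_pdms_m2s,D_gas_m2s oxygen diffusivity in PDMS and in nitrogen.
#' @param partition_gas_to_pdms equilibrium oxygen partition at the
#'   nitrogen-gas:PDMS interface. With `partition_gas_rich = TRUE` (default)
#'   it is read as C_gas : C_pdms = partition : 1 at equilibrium; the flag
#'   exposes the opposite reading.
#' @param partition_gas_rich see above.
#' @param inlet_velocity_ms mean (superficial) inlet velocity in the gas
#'   layer.
#' @param C_init_pct initial oxygen everywhere.
#' @param C_inlet_pct oxygen in the inlet gas (0 for humidified nitrogen).
#' @param C_outer_pct ambient oxygen at PDMS surfaces facing the outside.
#' @param t_end_s,output_dt_s simulated duration and output interval.
#' @param nx,ny_gas,ny_pdms grid cells along the channel, across the gas
#'   layer and across the PDMS layer.
#' @param dt_s solver time step (one implicit diffusion solve plus one
#'   implicit upwind advection sweep per step).
#' @param lateral_ambient clamp the two lateral (x = 0, x = L) PDMS faces to
#'   `C_outer_pct` as well. Default `FALSE`: the model is an unrolled
#'   serpentine, whose folds continue inside the slab, so the lateral cut
#'   faces are treated as symmetry (no-flux) planes; clamping them creates an
#'   artificial ambient-contact corner at the channel exit.
#' @param closed_box verification mode: all boundaries no-flux, no advection
#'   (total partition-weighted oxygen mass is then conserved).
#' @param advection set `FALSE` to disable flow (used with `closed_box`).
#' @return an `oxygen_config` object.
#' @export
oxygen_config <- function(channel_length_m = 0.040,
                          pdms_thickness_m = 5e-3,
                          channel_height_m = 5e-4,
                          D_pdms_m2s = 3.55e-9,
                          D_gas_m2s = 1e-5,
                          partition_gas_to_pdms = 10,
                          partition_gas_rich = TRUE,
                          inlet_velocity_ms = 0.285,
                          C_init_pct = 21,
                          C_inlet_pct = 0,
                          C_outer_pct = 21,
                          t_end_s = 600,
                          output_dt_s = 60,
                          nx = 2000, ny_gas = 20, ny_pdms = 100,
                          dt_s = 1,
                          lateral_ambient = FALSE,
                          closed_box = FALSE,
                          advection = !closed_box) {
  ek_assert(channel_length_m > 0 && pdms_thickness_m > 0 &&
              channel_height_m > 0, "all lengths must be positive")
  ek_assert(D_pdms_m2s > 0 && D_gas_m2s > 0, "diffusivities must be positive")
  ek_assert(partition_gas_to_pdms > 0, "partition must be positive")
  ek_assert(inlet_velocity_ms >= 0, "velocity must be non-negative")
  conc <- c(C_init_pct, C_inlet_pct, C_outer_pct)
  ek_assert(all(conc >= 0 & conc <= 100), "concentrations must be in [0,100]")
  ek_assert(t_end_s > 0 && output_dt_s > 0 && dt_s > 0,
            "times must be positive")
  ek_assert(nx >= 4 && ny_gas >= 2 && ny_pdms >= 2, "grid too coarse")
  structure(as.list(environment()), class = "oxygen_config")
}

#' Simulate oxygen removal in the device cross-section
#'
#' Finite-volume discretisation on a tensor grid, in the gas-equivalent
#' potential `phi` (continuous across the partition interface; the physical
#' concentration is `phi` in the gas and `phi / partition` in PDMS under the
#' default gas-rich reading). Time integration is backward Euler on the
#' combined operator: implicit diffusion in both layers plus implicit
#' first-order upwind advection along the gas layer (laminar profile). The
#' channel residence time (~0.1 s) is far below the diffusion timescales, so
#' the advective balance is quasi-steady within each step; treating both
#' terms in one sparse LU-factorised solve keeps that balance exact at any
#' step size. Boundary conditions: fixed inlet concentration at x = 0 in the
#' gas, fixed ambient on the PDMS top and lateral faces, no flux through the
#' glass floor, advective outflow at the channel exit.
#'
#' @param cfg an [oxygen_config()].
#' @return an `oxygen_field`: list with `x_m`, `y_m` (cell centres; gas layer
#'   first), `layer` (`"gas"`/`"pdms"` per y row), `times_s`, and `C_pct`, an
#'   `nx x ny x n_times` array of physical percent-oxygen values per layer.
#' @export
simulate_oxygen <- function(cfg = oxygen_config()) {
  ek_assert(inherits(cfg, "oxygen_config"), "cfg must be an oxygen_config")
  P <- cfg$partition_gas_to_pdms
  # solubility weight of the gas-equivalent potential phi: mass density in a
  # cell is S * phi, and physical concentration is S * phi / S_layer_ref
  S_gas <- 1
  S_pdms <- if (cfg$partition_gas_rich) 1 / P else P
  nx <- cfg$nx; nyg <- cfg$ny_gas; nyp <- cfg$ny_pdms
  ny <- nyg + nyp
  dx <- cfg$channel_length_m / nx
  dyg <- cfg$channel_height_m / nyg
  dyp <- cfg$pdms_thickness_m / nyp
  dy <- c(rep(dyg, nyg), rep(dyp, nyp))
  layer <- c(rep("gas", nyg), rep("pdms", nyp))
  Dv <- ifelse(layer == "gas", cfg$D_gas_m2s, cfg$D_pdms_m2s)
  Sv <- ifelse(layer == "gas", S_gas, S_pdms)
  x <- (seq_len(nx) - 0.5) * dx
  y <- cumsum(dy) - dy / 2

  n <- nx * ny
  idx <- function(i, j) (j - 1L) * nx + i
  vol <- rep(dy, each = nx) * dx            # per unit depth
  Svec <- rep(Sv, each = nx)

  # face conductances (series resistances of the two half-cells)
  cond <- function(d1, DS1, d2, DS2, A) A / (d1 / DS1 + d2 / DS2)
  DS <- Dv * Sv
  ii <- jj <- xx <- list(); b_fix <- numeric(n); diag_fix <- numeric(n)
  # x-direction faces
  if (nx > 1) {
    a <- idx(rep(1:(nx - 1), ny), rep(1:ny, each = nx - 1))
    b <- a + 1L
    g <- rep(DS / dx, each = nx - 1) * dy[rep(1:ny, each = nx - 1)]
    ii <- c(ii, list(a, b)); jj <- c(jj, list(b, a)); xx <- c(xx, list(-g, -g))
  }
  # y-direction faces (includes the partition interface via harmonic series)
  a <- idx(rep(1:nx, ny - 1), rep(1:(ny - 1), each = nx))
  b <- a + nx
  gy <- cond(dy[1:(ny - 1)] / 2, DS[1:(ny - 1)],
             dy[2:ny] / 2, DS[2:ny], dx)
  g <- rep(gy, each = nx)
  ii <- c(ii, list(a, b)); jj <- c(jj, list(b, a)); xx <- c(xx, list(-g, -g))

  phi_inlet <- cfg$C_inlet_pct * 1           # gas-phase potential
  phi_outer <- cfg$C_outer_pct / ifelse(cfg$partition_gas_rich, 1 / P, P)
  if (!cfg$closed_box) {
    # inlet (x = 0) Dirichlet in the gas layer
    cells <- idx(1L, 1:nyg)
    g <- (DS[1:nyg] / (dx / 2)) * dy[1:nyg]
    diag_fix[cells] <- diag_fix[cells] + g
    b_fix[cells] <- b_fix[cells] + g * phi_inlet
    # ambient Dirichlet: PDMS top face
    cells <- idx(1:nx, ny)
    g <- (DS[ny] / (dy[ny] / 2)) * dx
    diag_fix[cells] <- diag_fix[cells] + g
    b_fix[cells] <- b_fix[cells] + g * phi_outer
    # ambient Dirichlet on the lateral PDMS faces (optional; see
    # `lateral_ambient`)
    if (cfg$lateral_ambient) {
      for (side in c(1L, nx)) {
        cells <- idx(side, (nyg + 1L):ny)
        g <- (DS[(nyg + 1L):ny] / (dx / 2)) * dy[(nyg + 1L):ny]
        diag_fix[cells] <- diag_fix[cells] + g
        b_fix[cells] <- b_fix[cells] + g * phi_outer
      }
    }
  }

  # diffusive part of the row diagonals (negative off-diagonal conductances)
  ii <- unlist(ii); jj <- unlist(jj); xx <- unlist(xx)
  diag_diff <- -Matrix::rowSums(
    Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n)))

  # advection: first-order upwind along x in the gas layer, laminar (plane
  # Poiseuille) profile normalised to the stated mean velocity; the upwind
  # fluxes enter the implicit operator directly (outflow on the diagonal,
  # inflow from the upstream cell off-diagonal)
  if (cfg$advection && cfg$inlet_velocity_ms > 0) {
    yc <- (seq_len(nyg) - 0.5) / nyg          # fractional channel height
    u <- 6 * yc * (1 - yc)
    u <- u * cfg$inlet_velocity_ms / mean(u)
    adv_i <- adv_j <- adv_x <- list()
    for (j in seq_len(nyg)) {
      adv <- u[j] * dyg * S_gas               # mass flux per unit phi
      cells <- idx(1:nx, j)
      diag_fix[cells] <- diag_fix[cells] + adv      # outflow (east face)
      if (nx > 1) {                                  # inflow from the west
        adv_i <- c(adv_i, list(idx(2:nx, j)))
        adv_j <- c(adv_j, list(idx(1:(nx - 1), j)))
        adv_x <- c(adv_x, list(rep(-adv, nx - 1)))
      }
      b_fix[cells[1]] <- b_fix[cells[1]] + adv * phi_inlet
    }
    ii <- c(ii, unlist(adv_i)); jj <- c(jj, unlist(adv_j))
    xx <- c(xx, unlist(adv_x))
  }

  L <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
  mass <- vol * Svec / cfg$dt_s
  A <- L
  Matrix::diag(A) <- diag_diff + diag_fix + mass
  LU <- Matrix::lu(methods::as(A, "CsparseMatrix"))

  phi0 <- ifelse(layer == "gas", cfg$C_init_pct,
                 cfg$C_init_pct / ifelse(cfg$partition_gas_rich, 1 / P, P))
  phi <- rep(phi0, each = nx)

  out_every <- max(1L, round(cfg$output_dt_s / cfg$dt_s))
  nsteps <- ceiling(cfg$t_end_s / cfg$dt_s)
  to_conc <- function(phiv) {
    m <- matrix(phiv, nx, ny)
    sweep(m, 2L, ifelse(layer == "gas", 1,
                        ifelse(cfg$partition_gas_rich, 1 / P, P)), `*`)
  }
  times <- 0; snaps <- list(to_conc(phi))
  for (s in seq_len(nsteps)) {
    rhs <- mass * phi + b_fix
    phi <- as.numeric(Matrix::solve(LU, rhs))
    if (s %% out_every == 0L || s == nsteps) {
      times <- c(times, s * cfg$dt_s)
      snaps[[length(snaps) + 1L]] <- to_conc(phi)
    }
  }
  C <- array(unlist(snaps), dim = c(nx, ny, length(times)))
  structure(list(x_m = x, y_m = y, layer = layer, times_s = times,
                 C_pct = C, cfg = cfg),
            class = "oxygen_field")
}

#' Oxygen profile along the channel mid-height
#'
#' @param field an `oxygen_field` from [simulate_oxygen()].
#' @param t_s a stored output time (no interpolation between stored steps).
#' @return data frame `x_m`, `C_pct`.
#' @export
channel_profile <- function(field, t_s) {
  ti <- match(t_s, field$times_s)
  ek_assert(!is.na(ti), "t_s = ", t_s, " is not a stored output time; ",
            "stored: ", paste(field$times_s, collapse = ", "))
  mid <- max(1L, round(field$cfg$ny_gas / 2))
  data.frame(x_m = field$x_m, C_pct = field$C_pct[, mid, ti])
}

#' Maximum gas-channel concentration at a stored time
#'
#' @inheritParams channel_profile
#' @return percent oxygen, maximised over every gas-layer cell.
#' @export
channel_max <- function(field, t_s) {
  ti <- match(t_s, field$times_s)
  ek_assert(!is.na(ti), "t_s is not a stored output time")
  max(field$C_pct[, field$layer == "gas", ti])
}

#' Total dissolved oxygen mass in the cross-section
#'
#' The volume integral of the physical concentration (percent x m^2 per unit
#' depth). In the closed-box no-flux, no-flow configuration this is conserved
#' by the finite-volume scheme.
#'
#' @param field an `oxygen_field`.
#' @param t_s stored time (default: all stored times).
#' @return numeric vector of masses at the requested times.
#' @export
oxygen_total_mass <- function(field, t_s = field$times_s) {
  cfg <- field$cfg
  dx <- cfg$channel_length_m / cfg$nx
  dy <- c(rep(cfg$channel_height_m / cfg$ny_gas, cfg$ny_gas),
          rep(cfg$pdms_thickness_m / cfg$ny_pdms, cfg$ny_pdms))
  vapply(t_s, function(t) {
    ti <- match(t, field$times_s)
    ek_assert(!is.na(ti), "t_s is not a stored output time")
    sum(sweep(field$C_pct[, , ti], 2L, dy, `*`)) * dx
  }, numeric(1))
}
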