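#' Construct transport properties
#'
#' Defaults describe the differentiation-media tracer: free diffusion
#' coefficient 2.907e-9 m^2/s, reduced inside the collagen by a simple
#' porosity scaling (`porous_effective_D_factor`, default 0.90 to match
#' the collagen porosity).
#'
#' @param diffusion_coefficient free diffusion coefficient (m^2/s).
#' @param porous_effective_D_factor multiplier on `D` in POROUS voxels.
#' @return A validated `TransportProps` object.
#' @export
transportProps <- function(diffusion_coefficient = 2.907e-9,
                           porous_effective_D_factor = 0.90) {
  new("TransportProps", diffusion_coefficient = diffusion_coefficient,
      porous_effective_D_factor = porous_effective_D_factor)
}

#' Transport properties for the media tracer
#' @slot diffusion_coefficient m^2/s.
#' @slot porous_effective_D_factor effective-diffusivity factor in
#'   collagen (porosity scaling).
#' @export
setClass("TransportProps", representation(
  diffusion_coefficient = "numeric",
  porous_effective_D_factor = "numeric"
))
setValidity("TransportProps", function(object) {
  if (object@diffusion_coefficient <= 0) return("D must be > 0")
  if (object@porous_effective_D_factor <= 0 ||
      object@porous_effective_D_factor > 1) {
    return("porous_effective_D_factor must lie in (0, 1]")
  }
  TRUE
})

# Penalized solids get a vanishing effective diffusivity so the
# advective fluxes of the penalized flow field stay divergence-
# consistent; the resulting through-strut transport is negligible.
.SOLID_D_FACTOR <- 1e-9

# Effective diffusivity per cell.
.effD <- function(grid, props) {
  D <- array(NA_real_, dim(grid@label))
  D[grid@label == .LABELS[["LUMEN"]]] <- props@diffusion_coefficient
  D[grid@label == .LABELS[["POROUS"]]] <-
    props@diffusion_coefficient * props@porous_effective_D_factor
  D[grid@label == .LABELS[["SOLID"]]] <-
    props@diffusion_coefficient * .SOLID_D_FACTOR
  D
}

#' Solve steady advection-diffusion of the media tracer
#'
#' Finite-volume discretization on the same voxel grid as the flow:
#' advective face fluxes taken from the solved [FlowField-class],
#' harmonic-mean face diffusivities, Dirichlet concentrations on the
#' inlet port faces, zero diffusive flux at outlets (advective
#' outflow), and zero flux on walls. Advection uses the hybrid
#' upwind/central scheme: central differencing where the face Peclet
#' number is below 2 (second order there) and first-order upwinding
#' elsewhere, which keeps the discrete operator an M-matrix and hence
#' guarantees the maximum principle. The linear system is solved by
#' BiCGSTAB preconditioned with a Cholesky factorization of the
#' symmetric part.
#'
#' @param field converged [FlowField-class] on the same grid.
#' @param grid the [LabeledGrid-class].
#' @param props a `TransportProps` object.
#' @param inlet_conc optional named numeric (by chamber, e.g.
#'   `c(top = 1, bottom = 0)`) overriding the port table's inlet
#'   concentrations.
#' @param tol relative residual target.
#' @param max_iter BiCGSTAB iteration cap.
#' @return A [ConcentrationField-class]; `diagnostics` holds residuals
#'   and the tracer flux balance.
#' @export
solveTransport <- function(field, grid, props = transportProps(),
                           inlet_conc = NULL, tol = 1e-10,
                           max_iter = 5000L) {
  if (!isTRUE(field@diagnostics$converged)) {
    stop("flow field is not converged; refusing to transport on it")
  }
  setup <- .flowSetup(grid, bc = NULL)
  h <- setup$h
  pid <- setup$pid
  np <- setup$np
  Deff <- .effD(grid, props)
  uarr <- list(field@ux, field@uy, field@uz)
  ncell <- dim(grid@label)

  ti <- list(); tj <- list(); tx <- list()
  rhs <- numeric(np)
  push <- function(i, j, x) {
    k <- length(ti) + 1L
    ti[[k]] <<- i; tj[[k]] <<- j; tx[[k]] <<- x
  }

  for (d in 1:3) {
    fd <- .axisDims(d, ncell)
    cls <- setup$fc[[d]]
    # interior faces: flux between two included cells
    pos <- which(cls == .FC[["INTERIOR"]])
    if (length(pos)) {
      ijk <- arrayInd(pos, fd)
      Lijk <- ijk; Lijk[, d] <- ijk[, d] - 1L
      Lc <- pid[Lijk]; Rc <- pid[ijk]
      DL <- Deff[Lijk]; DR <- Deff[ijk]
      Dface <- 2 * DL * DR / (DL + DR)
      Fh <- uarr[[d]][pos] * h^2          # advective flux L -> R
      C <- Dface * h                       # diffusive conductance
      pe <- abs(uarr[[d]][pos]) * h / Dface
      central <- pe < 2
      # row L: outgoing F*c_face - C (c_R - c_L); row R gets the mirror
      aLL <- C + ifelse(central, Fh / 2, pmax(Fh, 0))
      aLR <- -C + ifelse(central, Fh / 2, pmin(Fh, 0))
      aRR <- C + ifelse(central, -Fh / 2, pmax(-Fh, 0))
      aRL <- -C + ifelse(central, -Fh / 2, pmin(-Fh, 0))
      push(Lc, Lc, aLL); push(Lc, Rc, aLR)
      push(Rc, Rc, aRR); push(Rc, Lc, aRL)
    }
    # inlet faces: Dirichlet concentration, advective inflow
    pos <- which(cls == .FC[["INLET"]])
    if (length(pos)) {
      sel <- setup$port_faces$axis == d &
        setup$port_faces$pos %in% pos
      pf <- setup$port_faces[sel, ]
      cin <- pf$conc
      if (!is.null(inlet_conc)) {
        ov <- match(pf$chamber, names(inlet_conc))
        cin[!is.na(ov)] <- inlet_conc[ov[!is.na(ov)]]
      }
      if (anyNA(cin)) stop("inlet port(s) without a concentration")
      cell <- pid[cbind(pf$ci, pf$cj, pf$ck)]
      m <- -pf$o * vapply(seq_len(nrow(pf)), function(i) {
        uarr[[d]][pf$pos[i]]
      }, numeric(1))                       # inflow speed (>= 0)
      Dc <- Deff[cbind(pf$ci, pf$cj, pf$ck)]
      Cb <- 2 * Dc * h                     # Dirichlet at h/2
      push(cell, cell, Cb + pmax(-m, 0) * h^2)
      rhs[cell] <- rhs[cell] + (Cb + pmax(m, 0) * h^2) * cin
    }
    # outlet faces: advective outflow of the cell value
    pos <- which(cls == .FC[["OUTLET"]])
    if (length(pos)) {
      sel <- setup$port_faces$axis == d &
        setup$port_faces$pos %in% pos
      pf <- setup$port_faces[sel, ]
      cell <- pid[cbind(pf$ci, pf$cj, pf$ck)]
      q <- pf$o * vapply(seq_len(nrow(pf)), function(i) {
        uarr[[d]][pf$pos[i]]
      }, numeric(1))                       # outflow speed
      push(cell, cell, q * h^2)
    }
  }
  M <- Matrix::sparseMatrix(
    i = unlist(ti), j = unlist(tj), x = unlist(tx), dims = c(np, np)
  )
  sol <- .bicgstab(M, rhs, tol = tol, max_iter = max_iter)
  if (!sol$converged) {
    stop(sprintf(
      "transport solve did not converge (residual %.3e after %d iterations)",
      sol$residual, sol$iterations
    ))
  }
  conc <- array(NA_real_, ncell)
  conc[setup$incl] <- sol$x

  # tracer flux balance: advective + diffusive in at inlets vs
  # advective out at outlets
  pb <- setup$port_faces
  influx <- 0; outflux <- 0
  for (i in seq_len(nrow(pb))) {
    uface <- uarr[[pb$axis[i]]][pb$pos[i]]
    cell <- conc[pb$ci[i], pb$cj[i], pb$ck[i]]
    if (pb$role[i] == "inlet") {
      cin <- pb$conc[i]
      if (!is.null(inlet_conc) && pb$chamber[i] %in% names(inlet_conc)) {
        cin <- inlet_conc[[pb$chamber[i]]]
      }
      m <- -pb$o[i] * uface
      Dc <- Deff[pb$ci[i], pb$cj[i], pb$ck[i]]
      adv <- if (m >= 0) m * h^2 * cin else m * h^2 * cell  # upwind value
      influx <- influx + adv + 2 * Dc * h * (cin - cell)
    } else {
      outflux <- outflux + pb$o[i] * uface * h^2 * cell
    }
  }
  balance <- abs(influx - outflux) /
    max(abs(influx), abs(outflux), .Machine$double.eps)

  new("ConcentrationField",
    conc = conc, spacing = h, origin = grid@origin,
    diagnostics = list(
      converged = TRUE, iterations = sol$iterations,
      residual = sol$residual, tracer_influx = influx,
      tracer_outflux = outflux, flux_balance = balance
    )
  )
}

# BiCGSTAB with a Cholesky preconditioner built from the symmetric part
# of the operator (SPD for a divergence-consistent advection field).
# Symmetric Jacobi scaling first: penalized solid rows are many orders
# smaller than lumen rows and would wreck the iteration otherwise.
.bicgstab <- function(M, b, tol = 1e-10, max_iter = 5000L) {
  s <- 1 / sqrt(pmax(Matrix::diag(M), .Machine$double.xmin))
  Ms <- Matrix::Diagonal(x = s) %*% M %*% Matrix::Diagonal(x = s)
  sol <- .bicgstabCore(methods::as(Ms, "CsparseMatrix"), s * b,
                       tol = tol, max_iter = max_iter)
  sol$x <- s * sol$x
  sol
}

.bicgstabCore <- function(M, b, tol = 1e-10, max_iter = 5000L) {
  n <- length(b)
  bn <- sqrt(sum(b^2))
  if (bn == 0) {
    return(list(x = numeric(n), converged = TRUE, iterations = 0L,
                residual = 0))
  }
  P <- Matrix::forceSymmetric((M + Matrix::t(M)) / 2)
  chP <- tryCatch(Matrix::Cholesky(P, LDL = FALSE), error = function(e) NULL)
  if (is.null(chP)) {
    # fall back to the SPD diffusion + advection-diagonal part
    P <- Matrix::Diagonal(n, Matrix::diag(M))
    chP <- Matrix::Cholesky(Matrix::forceSymmetric(P), LDL = FALSE)
  }
  prec <- function(v) as.numeric(Matrix::solve(chP, v, system = "A"))
  x <- prec(b)                     # warm start: symmetric-part solve
  r <- b - as.numeric(M %*% x)
  rn <- sqrt(sum(r^2)) / bn
  if (rn < tol) {
    return(list(x = x, converged = TRUE, iterations = 0L, residual = rn))
  }
  r0 <- r
  rho <- alpha <- omega <- 1
  v <- p <- numeric(n)
  for (it in seq_len(max_iter)) {
    rho1 <- sum(r0 * r)
    if (abs(rho1) < 1e-300) break
    beta <- (rho1 / rho) * (alpha / omega)
    p <- r + beta * (p - omega * v)
    ph <- prec(p)
    v <- as.numeric(M %*% ph)
    alpha <- rho1 / sum(r0 * v)
    s <- r - alpha * v
    if (sqrt(sum(s^2)) / bn < tol) {
      x <- x + alpha * ph
      return(list(x = x, converged = TRUE, iterations = it,
                  residual = sqrt(sum(s^2)) / bn))
    }
    sh <- prec(s)
    t <- as.numeric(M %*% sh)
    omega <- sum(t * s) / sum(t * t)
    x <- x + alpha * ph + omega * sh
    r <- s - omega * t
    rho <- rho1
    rn <- sqrt(sum(r^2)) / bn
    if (rn < tol) {
      return(list(x = x, converged = TRUE, iterations = it, residual = rn))
    }
  }
  list(x = x, converged = FALSE, iterations = max_iter, residual = rn)
}

#' Cell Peclet number report
#'
#' Distribution of the cell Peclet number `|u| h / D_eff` over fluid
#' voxels: the discretization-quality guard for the hybrid advection
#' scheme (central differencing is used below 2).
#'
#' @param field a [FlowField-class].
#' @param props a `TransportProps`.
#' @param grid the [LabeledGrid-class].
#' @return List with `mean`, `max`, `fraction_above_2`, and quartiles.
#' @export
pecletReport <- function(field, props, grid) {
  Deff <- .effD(grid, props)
  sp <- speedArray(field)
  sel <- grid@label %in% c(.LABELS[["LUMEN"]], .LABELS[["POROUS"]])
  pe <- sp[sel] * grid@spacing / Deff[sel]
  list(
    mean = mean(pe), max = max(pe),
    fraction_above_2 = mean(pe > 2),
    quartiles = stats::quantile(pe, c(0.25, 0.5, 0.75))
  )
}

#' Flux-weighted outlet mixing fractions
#'
#' Flux-weighted mean outlet concentration per chamber, converted to a
#' mixing fraction: the top (chondrogenic, inlet c = 1) chamber's mixing
#' is `1 - <c>` at its outlets, the bottom (osteogenic, inlet c = 0)
#' chamber's is `<c>` -- i.e. the fraction of "foreign" medium leaving
#' each chamber.
#'
#' @param conc a [ConcentrationField-class].
#' @param field the [FlowField-class] used to produce it.
#' @param bc the [FlowBC-class] (interface completeness; fluxes come
#'   from the solved field).
#' @return Named numeric: mixing fraction for `top` and `bottom`.
#' @export
outletMixing <- function(conc, field, bc = flowBC()) {
  pb <- field@diagnostics$port_faces
  if (is.null(pb)) stop("flow field carries no port face table")
  out <- pb[pb$role == "outlet", ]
  h <- field@spacing
  uarr <- list(field@ux, field@uy, field@uz)
  res <- c(top = NA_real_, bottom = NA_real_)
  for (ch in intersect(unique(out$chamber), names(res))) {
    sel <- out[out$chamber == ch, ]
    q <- vapply(seq_len(nrow(sel)), function(i) {
      sel$o[i] * uarr[[sel$axis[i]]][sel$pos[i]] * h^2
    }, numeric(1))
    cv <- conc@conc[cbind(sel$ci, sel$cj, sel$ck)]
    if (sum(q) <= 0) stop(sprintf("zero outlet flux in chamber '%s'", ch))
    cbar <- sum(q * cv) / sum(q)
    res[ch] <- if (ch == "top") 1 - cbar else cbar
  }
  res
}

setMethod("show", "ConcentrationField", function(object) {
  v <- object@conc[!is.na(object@conc)]
  cat(sprintf(
    "ConcentrationField: range [%.4g, %.4g], tracer flux balance %.2e\n",
    min(v), max(v), object@diagnostics$flux_balance %||% NA_real_
  ))
})
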