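# Staggered (MAC) finite-volume Stokes-Brinkman solver with solid
# penalization. One Brinkman momentum equation covers the whole fluid
# domain: mu lap(u) - grad p - (mu / k(x)) u = 0, div u = 0, with
# k = Inf in the lumen (drag off), the collagen permeability in POROUS
# voxels, and a vanishing penalization permeability in SOLID voxels.
# Discrete system (face volume scaling):
#   (mu h^3 / k_f) u_f + mu h sum_nb (u_f - u_nb) + h^2 (p_R - p_L) = 0
#   sum_faces +/- h^2 u_f = 0  per cell
# solved monolithically by a Schur-complement (Uzawa) PCG: the three
# SPD momentum blocks are factored once with CHOLMOD, CG runs on
# S = G' A^-1 G with the SIMPLE-type preconditioner G' diag(A)^-1 G.

.axisDims <- function(d, ncell) {
  fd <- ncell
  fd[d] <- fd[d] + 1L
  fd
}

# face classification codes
.FC <- c(NONE = 0L, INTERIOR = 1L, OUTLET = 2L, INLET = 3L, WALL = 4L)

# Shifted inclusion masks for the face grid of axis `d`.
.faceNeighborsIncl <- function(incl, d) {
  ncell <- dim(incl)
  fd <- .axisDims(d, ncell)
  Lincl <- array(FALSE, fd)
  Rincl <- array(FALSE, fd)
  ix <- function(n) seq_len(n)
  if (d == 1L) {
    Lincl[ix(ncell[1]) + 1L, , ] <- incl
    Rincl[ix(ncell[1]), , ] <- incl
  } else if (d == 2L) {
    Lincl[, ix(ncell[2]) + 1L, ] <- incl
    Rincl[, ix(ncell[2]), ] <- incl
  } else {
    Lincl[, , ix(ncell[3]) + 1L] <- incl
    Rincl[, , ix(ncell[3])] <- incl
  }
  list(L = Lincl, R = Rincl)
}

# Physical centre of face (i,j,k) of axis d.
.faceCenters <- function(ijk, d, h, origin) {
  ctr <- (ijk - 0.5) * h
  ctr[, d] <- (ijk[, d] - 1) * h
  sweep(ctr, 2, origin, "+")
}

# Classify every face of every axis; match boundary faces to ports and
# compute imposed inlet velocities. Returns the full face bookkeeping
# used by assembly, diagnostics, and the transport solver. With
# `bc = NULL` only the topology is built (inlet velocities left 0),
# which is what the transport solver needs.
.flowSetup <- function(grid, bc = NULL) {
  h <- grid@spacing
  L <- grid@label
  ncell <- dim(L)
  incl <- L != .LABELS[["WALL"]]
  if (!any(incl)) stop("grid has no fluid cells")
  pid <- array(NA_integer_, ncell)
  pid[incl] <- seq_len(sum(incl))
  np <- sum(incl)

  ports <- grid@ports
  if (!nrow(ports)) stop("grid carries no ports; domain sealed")
  ports$id <- seq_len(nrow(ports))
  n_inlets <- table(ports$chamber[ports$role == "inlet"])

  fc <- vector("list", 3)
  fv <- vector("list", 3)
  face_rows <- list()
  for (d in 1:3) {
    fd <- .axisDims(d, ncell)
    nb <- .faceNeighborsIncl(incl, d)
    cls <- array(.FC[["NONE"]], fd)
    cls[nb$L & nb$R] <- .FC[["INTERIOR"]]
    bndP <- nb$L & !nb$R   # wall on + side
    bndM <- !nb$L & nb$R   # wall on - side
    cls[bndP | bndM] <- .FC[["WALL"]]
    val <- array(0, fd)
    bpos <- which(bndP | bndM)
    if (length(bpos)) {
      o <- ifelse(bndP[bpos], 1, -1)
      ijk <- arrayInd(bpos, fd)
      ctr <- .faceCenters(ijk, d, h, grid@origin)
      # interior cell flanking the boundary face
      cell <- ijk
      cell[, d] <- ijk[, d] - as.integer(o == 1)
      face_rows[[d]] <- data.frame(
        axis = d, pos = bpos, o = o,
        ci = cell[, 1], cj = cell[, 2], ck = cell[, 3],
        fx = ctr[, 1], fy = ctr[, 2], fz = ctr[, 3]
      )
    }
    fc[[d]] <- cls
    fv[[d]] <- val
  }
  bfaces <- do.call(rbind, face_rows)

  # match boundary faces to ports (ball around the port centre + normal
  # alignment); ports feed open fluid only, never penalized solid
  bfaces$port <- NA_integer_
  open_cell <- L[cbind(bfaces$ci, bfaces$cj, bfaces$ck)] %in%
    c(.LABELS[["LUMEN"]], .LABELS[["POROUS"]])
  for (pidx in seq_len(nrow(ports))) {
    pt <- ports[pidx, ]
    dx <- bfaces$fx - pt$px; dy <- bfaces$fy - pt$py; dz <- bfaces$fz - pt$pz
    dist2 <- dx^2 + dy^2 + dz^2
    nport <- c(pt$nx, pt$ny, pt$nz)
    align <- bfaces$o * nport[bfaces$axis]
    sel <- is.na(bfaces$port) & open_cell &
      dist2 <= (pt$diameter / 2 + h / 2)^2 & align > 0.3
    if (!any(sel)) {
      stop(sprintf(
        "port %d (%s, %s chamber) matches no boundary faces; check port placement/resolution",
        pidx, pt$role, pt$chamber
      ))
    }
    bfaces$port[sel] <- pidx
  }
  pb <- bfaces[!is.na(bfaces$port), ]
  pb$role <- ports$role[pb$port]
  pb$chamber <- ports$chamber[pb$port]
  pb$conc <- ports$conc[pb$port]
  pb$u <- 0
  for (i in seq_len(nrow(pb))) {
    fc[[pb$axis[i]]][pb$pos[i]] <-
      if (pb$role[i] == "inlet") .FC[["INLET"]] else .FC[["OUTLET"]]
  }
  if (!is.null(bc) && !any(pb$role == "outlet")) {
    stop("domain sealed: no outlet faces")
  }

  # imposed inlet velocities: parabolic (or uniform) weights over the
  # port disc, rescaled so the discrete flux is exactly the port flow
  for (pidx in if (is.null(bc)) integer(0) else
       unique(pb$port[pb$role == "inlet"])) {
    pt <- ports[pidx, ]
    ch <- pt$chamber
    if (!ch %in% names(bc@inlet_flow_rate)) {
      stop(sprintf("no inlet flow rate given for chamber '%s'", ch))
    }
    qport <- bc@inlet_flow_rate[[ch]] / as.integer(n_inlets[[ch]])
    sel <- which(pb$port == pidx)
    dxyz <- cbind(pb$fx[sel] - pt$px, pb$fy[sel] - pt$py, pb$fz[sel] - pt$pz)
    npt <- c(pt$nx, pt$ny, pt$nz)
    along <- dxyz %*% npt
    perp2 <- rowSums(dxyz^2) - along^2
    w <- if (pt$profile == "uniform") rep(1, length(sel)) else {
      pmax(1 - perp2 / (pt$diameter / 2)^2, 0.05)
    }
    m <- w * (qport / (sum(w) * h^2))  # normal speed, inflow positive
    pb$u[sel] <- -pb$o[sel] * m        # velocity along +axis
    for (r in seq_along(sel)) {
      i <- sel[r]
      fv[[pb$axis[i]]][pb$pos[i]] <- pb$u[i]
    }
  }

  # unknown face numbering (interior + outlet), contiguous across axes
  fid <- vector("list", 3)
  nunk <- integer(3)
  off <- 0L
  for (d in 1:3) {
    cls <- fc[[d]]
    unk <- cls == .FC[["INTERIOR"]] | cls == .FC[["OUTLET"]]
    ids <- array(NA_integer_, dim(cls))
    nunk[d] <- sum(unk)
    ids[unk] <- off + seq_len(nunk[d])
    off <- off + nunk[d]
    fid[[d]] <- ids
  }

  list(
    incl = incl, pid = pid, np = np, fc = fc, fv = fv, fid = fid,
    nunk = nunk, ntot = off, ports = ports, port_faces = pb, h = h
  )
}

# Assemble the three SPD momentum blocks, the gradient operator G, and
# the right-hand sides.
.assembleStokes <- function(grid, setup, fluid, porous, bc) {
  h <- setup$h
  mu <- fluid@dynamic_viscosity
  L <- grid@label
  ncell <- dim(L)
  invk <- array(NA_real_, ncell)
  invk[L == .LABELS[["LUMEN"]]] <- 0
  invk[L == .LABELS[["POROUS"]]] <- 1 / porous@permeability
  invk[L == .LABELS[["SOLID"]]] <- 1 / porous@solid_penalization_k
  pid <- setup$pid
  p0 <- bc@outlet_pressure

  Ablocks <- vector("list", 3)
  Gtrip <- list(i = list(), j = list(), x = list())
  b_u <- numeric(setup$ntot)
  b_div <- numeric(setup$np)

  unit <- diag(3)
  for (d in 1:3) {
    fd <- .axisDims(d, ncell)
    ids <- setup$fid[[d]]
    pos <- which(!is.na(ids))
    if (!length(pos)) { Ablocks[[d]] <- NULL; next }
    rows_global <- ids[pos]
    row_local <- seq_along(pos)
    ijk <- arrayInd(pos, fd)
    n <- length(pos)
    # flanking cells
    Lijk <- ijk; Lijk[, d] <- ijk[, d] - 1L
    Rijk <- ijk
    inL <- Lijk[, d] >= 1L
    inR <- Rijk[, d] <= ncell[d]
    Lpid <- rep(NA_integer_, n); Rpid <- rep(NA_integer_, n)
    Lpid[inL] <- pid[Lijk[inL, , drop = FALSE]]
    Rpid[inR] <- pid[Rijk[inR, , drop = FALSE]]
    invkL <- rep(NA_real_, n); invkR <- rep(NA_real_, n)
    invkL[inL] <- invk[Lijk[inL, , drop = FALSE]]
    invkR[inR] <- invk[Rijk[inR, , drop = FALSE]]
    invkf <- rowMeans(cbind(invkL, invkR), na.rm = TRUE)

    dvec <- mu * h^3 * invkf      # drag on the diagonal
    ti <- list(); tj <- list(); tx <- list()
    rhs <- numeric(n)
    for (e in 1:3) for (s in c(-1L, 1L)) {
      nb <- ijk
      nb[, e] <- ijk[, e] + s
      ok <- nb[, e] >= 1L & nb[, e] <= fd[e]
      cls <- rep(.FC[["NONE"]], n)
      nbpos <- rep(NA_integer_, n)
      if (any(ok)) {
        nbl <- nb[ok, , drop = FALSE]
        lin <- nbl[, 1] + (nbl[, 2] - 1L) * fd[1] +
          (nbl[, 3] - 1L) * fd[1] * fd[2]
        cls[ok] <- setup$fc[[d]][lin]
        nbpos[ok] <- lin
      }
      isU <- cls == .FC[["INTERIOR"]] | cls == .FC[["OUTLET"]]
      if (any(isU)) {
        ti[[length(ti) + 1L]] <- row_local[isU]
        tj[[length(tj) + 1L]] <- setup$fid[[d]][nbpos[isU]] -
          (rows_global[1] - row_local[1])  # local column index
        tx[[length(tx) + 1L]] <- rep(-mu * h, sum(isU))
        dvec[isU] <- dvec[isU] + mu * h
      }
      isI <- cls == .FC[["INLET"]]
      if (any(isI)) {
        rhs[isI] <- rhs[isI] + mu * h * setup$fv[[d]][nbpos[isI]]
        dvec[isI] <- dvec[isI] + mu * h
      }
      isW <- cls == .FC[["WALL"]]
      dvec[isW] <- dvec[isW] + mu * h
      isN <- cls == .FC[["NONE"]]
      if (e != d && any(isN) && !bc@slip_axes[e]) {
        # wall plane at half a cell: no-slip ghost
        dvec[isN] <- dvec[isN] + 2 * mu * h
      }
      # e == d missing neighbour: zero-gradient (outlet far side)
    }
    ti[[length(ti) + 1L]] <- row_local
    tj[[length(tj) + 1L]] <- row_local
    tx[[length(tx) + 1L]] <- dvec
    Ablocks[[d]] <- Matrix::sparseMatrix(
      i = unlist(ti), j = unlist(tj), x = unlist(tx), dims = c(n, n)
    )

    # pressure gradient + known-pressure RHS
    hasL <- !is.na(Lpid); hasR <- !is.na(Rpid)
    Gtrip$i[[d]] <- c(rows_global[hasR], rows_global[hasL])
    Gtrip$j[[d]] <- c(Rpid[hasR], Lpid[hasL])
    Gtrip$x[[d]] <- c(rep(h^2, sum(hasR)), rep(-h^2, sum(hasL)))
    rhs[!hasR] <- rhs[!hasR] - h^2 * p0  # ghost p_R = outlet pressure
    rhs[!hasL] <- rhs[!hasL] + h^2 * p0  # ghost p_L = outlet pressure
    b_u[rows_global] <- rhs

    # divergence RHS from imposed inlet faces
    inlet_pos <- which(setup$fc[[d]] == .FC[["INLET"]])
    if (length(inlet_pos)) {
      ii <- arrayInd(inlet_pos, fd)
      v <- setup$fv[[d]][inlet_pos]
      # wall on + side -> face is + face of cell (i-1); else - face of (i)
      Lc <- ii; Lc[, d] <- ii[, d] - 1L
      isP <- Lc[, d] >= 1L & {
        tmp <- rep(FALSE, length(inlet_pos))
        okL <- Lc[, d] >= 1L
        tmp[okL] <- setup$incl[Lc[okL, , drop = FALSE]]
        tmp
      }
      cellP <- pid[Lc[isP, , drop = FALSE]]
      b_div[cellP] <- b_div[cellP] - v[isP] * h^2
      Rc <- ii[!isP, , drop = FALSE]
      cellM <- pid[Rc]
      b_div[cellM] <- b_div[cellM] + v[!isP] * h^2
    }
  }
  iG <- unlist(Gtrip$i); jG <- unlist(Gtrip$j); xG <- unlist(Gtrip$x)
  G <- Matrix::sparseMatrix(i = iG, j = jG, x = xG,
                            dims = c(setup$ntot, setup$np))
  list(A = Ablocks, G = G, b_u = b_u, b_div = b_div)
}

.uzawaSolve <- function(sys, setup, tol, max_iter, verbose = FALSE) {
  nunk <- setup$nunk
  offs <- cumsum(c(0L, nunk))
  chols <- vector("list", 3)
  for (d in 1:3) {
    if (nunk[d] > 0) {
      chols[[d]] <- Matrix::Cholesky(Matrix::forceSymmetric(sys$A[[d]]),
                                     LDL = FALSE)
    }
  }
  Asolve <- function(v) {
    out <- numeric(length(v))
    for (d in 1:3) {
      if (nunk[d] > 0) {
        idx <- (offs[d] + 1L):offs[d + 1L]
        out[idx] <- as.numeric(Matrix::solve(chols[[d]], v[idx],
                                             system = "A"))
      }
    }
    out
  }
  G <- sys$G
  keep <- Matrix::colSums(abs(G)) > 0
  Gk <- G[, keep, drop = FALSE]
  dA <- numeric(sum(nunk))
  for (d in 1:3) {
    if (nunk[d] > 0) {
      idx <- (offs[d] + 1L):offs[d + 1L]
      dA[idx] <- Matrix::diag(sys$A[[d]])
    }
  }
  P <- Matrix::crossprod(Gk, Gk / dA)
  P <- P + Matrix::Diagonal(ncol(P), 1e-10 * mean(Matrix::diag(P)))
  chP <- Matrix::Cholesky(Matrix::forceSymmetric(P), LDL = FALSE)
  Psolve <- function(r) as.numeric(Matrix::solve(chP, r, system = "A"))
  Sapply <- function(p) {
    as.numeric(Matrix::crossprod(Gk, Asolve(as.numeric(Gk %*% p))))
  }

  rhs <- as.numeric(Matrix::crossprod(Gk, Asolve(sys$b_u))) +
    sys$b_div[keep]
  npk <- length(rhs)
  p <- numeric(npk)
  r <- rhs
  rhs_norm <- sqrt(sum(rhs^2))
  iters <- 0L
  hist <- numeric(0)
  converged <- TRUE
  if (rhs_norm > 0) {
    z <- Psolve(r)
    dvec <- z
    rz <- sum(r * z)
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      Sd <- Sapply(dvec)
      alpha <- rz / sum(dvec * Sd)
      p <- p + alpha * dvec
      r <- r - alpha * Sd
      rn <- sqrt(sum(r^2)) / rhs_norm
      hist <- c(hist, rn)
      iters <- it
      if (rn < tol) { converged <- TRUE; break }
      z <- Psolve(r)
      rz_new <- sum(r * z)
      dvec <- z + (rz_new / rz) * dvec
      rz <- rz_new
    }
  }
  u <- Asolve(sys$b_u - as.numeric(G %*% .expandP(p, keep, setup$np)))
  list(u = u, p = .expandP(p, keep, setup$np), iterations = iters,
       converged = converged, residual_history = hist,
       final_residual = if (length(hist)) tail(hist, 1) else 0)
}

.expandP <- function(p, keep, np) {
  out <- numeric(np)
  out[keep] <- p
  out
}

#' Solve steady Stokes-Brinkman flow on a labeled grid
#'
#' Solves the unified creeping-flow Brinkman system on the staggered
#' voxel grid: viscous flow in the lumen, Brinkman flow in collagen
#' (POROUS) voxels, and penalized near-zero flow in PLA (SOLID) voxels,
#' with an imposed inlet velocity profile integrating exactly to the
#' prescribed chamber flow rate, fixed outlet pressure, and no-slip
#' walls. Inertia is omitted (the operating Reynolds number is well
#' below 1, see [reynoldsNumber()]); `picard` optional iterations add
#' the convective term explicitly for verification at higher rates.
#'
#' The momentum blocks are factored once (sparse Cholesky) and the
#' pressure Schur complement is solved by preconditioned conjugate
#' gradients; `tol` bounds the relative continuity residual, so mass
#' conservation at the reported tolerance is part of the solver
#' contract.
#'
#' @param grid a [LabeledGrid-class] with ports.
#' @param fluid a [FluidProps-class].
#' @param porous a [PorousProps-class].
#' @param bc a [FlowBC-class].
#' @param tol relative continuity residual target.
#' @param max_iter maximum Schur-CG iterations.
#' @param picard number of explicit convective (Picard) corrections;
#'   0 keeps the linear creeping-flow path.
#' @param verbose print residual progress.
#' @return A [FlowField-class]. `diagnostics` holds the residual
#'   history, per-port flux table (`port_flux`), per-face port
#'   bookkeeping (`port_faces`), and the continuity residual.
#' @examples
#' \donttest{
#' grid <- voxelize(buildLattice(scaffoldSpec()), chamberSpec(),
#'                  voxel_spacing = 500e-6)
#' field <- solveFlow(grid)
#' }
#' @export
solveFlow <- function(grid, fluid = fluidProps(), porous = porousProps(),
                      bc = flowBC(), tol = 1e-10, max_iter = 10000L,
                      picard = 0L, verbose = FALSE) {
  setup <- .flowSetup(grid, bc)
  sys <- .assembleStokes(grid, setup, fluid, porous, bc)
  sol <- .uzawaSolve(sys, setup, tol, max_iter, verbose)
  if (!sol$converged) {
    stop(sprintf(
      "flow solve did not converge in %d iterations (residual %.3e); residual history in `last_flow_residuals`",
      max_iter, sol$final_residual
    ))
  }
  field <- .buildFlowField(grid, setup, sol, bc)
  if (picard > 0L) {
    rho <- fluid@density
    for (it in seq_len(picard)) {
      conv <- .convectiveRHS(field, setup, rho)
      sys2 <- sys
      sys2$b_u <- sys$b_u - conv
      sol <- .uzawaSolve(sys2, setup, tol, max_iter, verbose)
      field <- .buildFlowField(grid, setup, sol, bc)
    }
  }
  field
}

.buildFlowField <- function(grid, setup, sol, bc) {
  ncell <- dim(grid@label)
  h <- setup$h
  uarr <- vector("list", 3)
  for (d in 1:3) {
    a <- array(0, .axisDims(d, ncell))
    ids <- setup$fid[[d]]
    sel <- which(!is.na(ids))
    a[sel] <- sol$u[ids[sel]]
    inlet <- which(setup$fc[[d]] == .FC[["INLET"]])
    a[inlet] <- setup$fv[[d]][inlet]
    uarr[[d]] <- a
  }
  p <- array(NA_real_, ncell)
  p[setup$incl] <- sol$p
  # per-face and per-port fluxes (outward-positive for outlets,
  # inward-positive for inlets)
  pb <- setup$port_faces
  pb$u <- vapply(seq_len(nrow(pb)), function(i) {
    uarr[[pb$axis[i]]][pb$pos[i]]
  }, numeric(1))
  pb$flux <- ifelse(pb$role == "inlet", -pb$o * pb$u, pb$o * pb$u) * h^2
  agg <- aggregate(flux ~ port, data = pb, FUN = sum)
  ports <- setup$ports
  pf <- data.frame(
    port = ports$id, role = ports$role, chamber = ports$chamber,
    flux = agg$flux[match(ports$id, agg$port)]
  )
  # continuity residual over included cells
  div <- (uarr[[1]][-1, , , drop = FALSE] -
            uarr[[1]][-(ncell[1] + 1L), , , drop = FALSE]) +
    (uarr[[2]][, -1, , drop = FALSE] -
       uarr[[2]][, -(ncell[2] + 1L), , drop = FALSE]) +
    (uarr[[3]][, , -1, drop = FALSE] -
       uarr[[3]][, , -(ncell[3] + 1L), drop = FALSE])
  div <- div * h^2
  qscale <- max(sum(pf$flux[pf$role == "inlet"], na.rm = TRUE),
                max(abs(sol$u)) * h^2, .Machine$double.eps)
  rel_div <- max(abs(div[setup$incl])) / qscale
  new("FlowField",
    ux = uarr[[1]], uy = uarr[[2]], uz = uarr[[3]], p = p,
    spacing = h, origin = grid@origin,
    diagnostics = list(
      converged = sol$converged, iterations = sol$iterations,
      residual_history = sol$residual_history,
      continuity_residual = rel_div,
      schur_residual = sol$final_residual,
      port_flux = pf, port_faces = pb,
      outlet_pressure = bc@outlet_pressure
    )
  )
}

# Explicit first-order upwind convective term rho (u . grad) u evaluated
# on the face grids of the current field; returned on unknown faces.
.convectiveRHS <- function(field, setup, rho) {
  h <- field@spacing
  u <- list(field@ux, field@uy, field@uz)
  out <- numeric(setup$ntot)
  for (d in 1:3) {
    ids <- setup$fid[[d]]
    pos <- which(!is.na(ids))
    if (!length(pos)) next
    fd <- dim(u[[d]])
    ijk <- arrayInd(pos, fd)
    conv <- numeric(length(pos))
    for (e in 1:3) {
      # advecting velocity component e at the d-face (average of the
      # four surrounding e-faces; same-face value when e == d)
      if (e == d) {
        ue <- u[[d]][pos]
      } else {
        a <- ijk; b <- ijk; cc <- ijk; dd <- ijk
        b[, e] <- b[, e] + 1L
        cc[, d] <- cc[, d] - 1L
        dd[, e] <- dd[, e] + 1L; dd[, d] <- dd[, d] - 1L
        fde <- dim(u[[e]])
        gv <- function(m) {
          okm <- m[, 1] >= 1 & m[, 1] <= fde[1] & m[, 2] >= 1 &
            m[, 2] <= fde[2] & m[, 3] >= 1 & m[, 3] <= fde[3]
          v <- numeric(nrow(m))
          v[okm] <- u[[e]][m[okm, , drop = FALSE]]
          v
        }
        ue <- 0.25 * (gv(a) + gv(b) + gv(cc) + gv(dd))
      }
      up <- ijk; up[, e] <- up[, e] + 1L
      dn <- ijk; dn[, e] <- dn[, e] - 1L
      gvd <- function(m) {
        okm <- m[, 1] >= 1 & m[, 1] <= fd[1] & m[, 2] >= 1 &
          m[, 2] <= fd[2] & m[, 3] >= 1 & m[, 3] <= fd[3]
        v <- u[[d]][pos]  # replicate own value outside (zero gradient)
        v[okm] <- u[[d]][m[okm, , drop = FALSE]]
        v
      }
      dplus <- (gvd(up) - u[[d]][pos]) / h
      dminus <- (u[[d]][pos] - gvd(dn)) / h
      conv <- conv + ue * ifelse(ue > 0, dminus, dplus)
    }
    out[ids[pos]] <- rho * conv * h^3
  }
  out
}
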