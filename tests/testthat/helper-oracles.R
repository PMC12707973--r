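# Independent reference implementations used as oracles. These are written
# from scratch against the same physics/maths, structured differently from
# the package code (vectorized over photons, R RNG, no stream derivation),
# so agreement is a genuine cross-check.

# --- reference photon transport -------------------------------------------
# Vectorized photon-packet transport through a finite layered slab; tallies
# total diffuse reflectance/transmittance over all exit radii. The free
# path is resampled after each boundary crossing (valid by memorylessness
# of the exponential). Returns fractions plus standard errors.
ref_mc_transport <- function(layers, ambient_n = 1, photons = 1e4,
                             seed = 1) {
  set.seed(seed)
  nl <- nrow(layers)
  zb <- c(0, cumsum(layers$thickness))
  rsp <- ((ambient_n - layers$n[1]) / (ambient_n + layers$n[1]))^2
  N <- as.integer(photons)
  z <- rep(0, N); ux <- rep(0, N); uy <- rep(0, N); uz <- rep(1, N)
  w <- rep(1 - rsp, N); lay <- rep(1L, N)
  alive <- rep(TRUE, N)
  refl_w <- rep(0, N); trans_w <- rep(0, N)
  absorbed <- 0
  fresnel_v <- function(ci, n1, n2) {
    R <- numeric(length(ci)); ct <- numeric(length(ci))
    same <- n1 == n2
    R[same] <- 0; ct[same] <- ci[same]
    m <- !same
    if (any(m)) {
      si <- sqrt(pmax(0, 1 - ci[m]^2))
      st <- n1[m] / n2[m] * si
      tir <- st >= 1
      ctm <- sqrt(pmax(0, 1 - st^2))
      rs <- (n1[m] * ci[m] - n2[m] * ctm) / (n1[m] * ci[m] + n2[m] * ctm)
      rp <- (n1[m] * ctm - n2[m] * ci[m]) / (n1[m] * ctm + n2[m] * ci[m])
      Rm <- 0.5 * (rs^2 + rp^2)
      Rm[tir] <- 1; ctm[tir] <- 0
      R[m] <- Rm; ct[m] <- ctm
    }
    list(R = R, ct = ct)
  }
  it <- 0
  while (any(alive) && (it <- it + 1) < 1e5) {
    i <- which(alive)
    mua <- layers$mu_a[lay[i]]; mus <- layers$mu_s[lay[i]]
    mt <- mua + mus
    s <- -log(runif(length(i))) / mt
    zhi <- zb[lay[i] + 1]; zlo <- zb[lay[i]]
    db <- rep(Inf, length(i))
    up <- uz[i] < 0; dn <- uz[i] > 0
    db[dn] <- (zhi[dn] - z[i][dn]) / uz[i][dn]
    db[up] <- (zlo[up] - z[i][up]) / uz[i][up]
    hit <- s >= db
    step <- pmin(s, db)
    z[i] <- z[i] + uz[i] * step

    # interactions
    j <- i[!hit]
    if (length(j)) {
      frac <- layers$mu_a[lay[j]] / (layers$mu_a[lay[j]] +
                                       layers$mu_s[lay[j]])
      dw <- w[j] * frac
      absorbed <- absorbed + sum(dw)
      w[j] <- w[j] - dw
      g <- layers$g[lay[j]]
      u1 <- runif(length(j))
      ct <- ifelse(abs(g) < 1e-12, 2 * u1 - 1, {
        tmp <- (1 - g^2) / (1 - g + 2 * g * u1)
        pmin(1, pmax(-1, (1 + g^2 - tmp^2) / (2 * g)))
      })
      st <- sqrt(pmax(0, 1 - ct^2))
      ph <- 2 * pi * runif(length(j))
      cp <- cos(ph); sp <- sin(ph)
      nearz <- abs(uz[j]) > 0.99999
      # general rotation
      den <- sqrt(pmax(1e-30, 1 - uz[j]^2))
      nux <- st * (ux[j] * uz[j] * cp - uy[j] * sp) / den + ux[j] * ct
      nuy <- st * (uy[j] * uz[j] * cp + ux[j] * sp) / den + uy[j] * ct
      nuz <- -st * cp * den + uz[j] * ct
      nux[nearz] <- (st * cp)[nearz]
      nuy[nearz] <- (st * sp)[nearz]
      nuz[nearz] <- (ct * sign(uz[j]))[nearz]
      ux[j] <- nux; uy[j] <- nuy; uz[j] <- nuz
      # roulette
      small <- w[j] < 1e-4
      if (any(small)) {
        k <- j[small]
        surv <- runif(length(k)) < 0.1
        absorbed <- absorbed + sum(w[k][!surv])
        alive[k[!surv]] <- FALSE
        w[k[surv]] <- w[k[surv]] / 0.1
      }
    }

    # boundary crossings
    j <- i[hit]
    if (length(j)) {
      going_up <- uz[j] < 0
      bidx <- ifelse(going_up, lay[j], lay[j] + 1L) # boundary 1..nl+1
      n1 <- layers$n[lay[j]]
      n2 <- ifelse(bidx == 1, ambient_n,
                   ifelse(bidx == nl + 1, ambient_n,
                          layers$n[ifelse(going_up, pmax(lay[j] - 1L, 1L),
                                          pmin(lay[j] + 1L, nl))]))
      fr <- fresnel_v(abs(uz[j]), n1, n2)
      refl_evt <- runif(length(j)) <= fr$R
      # reflected at the boundary
      uz[j[refl_evt]] <- -uz[j[refl_evt]]
      # transmitted
      k <- j[!refl_evt]
      if (length(k)) {
        bk <- bidx[!refl_evt]; gu <- going_up[!refl_evt]
        ctk <- fr$ct[!refl_evt]
        exit_top <- bk == 1 & gu
        exit_bot <- bk == nl + 1 & !gu
        esc <- exit_top | exit_bot
        refl_w[k[exit_top]] <- w[k[exit_top]]
        trans_w[k[exit_bot]] <- w[k[exit_bot]]
        alive[k[esc]] <- FALSE
        kk <- k[!esc]
        if (length(kk)) {
          gk <- gu[!esc]
          scale <- (layers$n[lay[kk]] /
                      layers$n[ifelse(gk, lay[kk] - 1L, lay[kk] + 1L)])
          ux[kk] <- ux[kk] * scale
          uy[kk] <- uy[kk] * scale
          uz[kk] <- ifelse(gk, -ctk[!esc], ctk[!esc])
          nrm <- sqrt(ux[kk]^2 + uy[kk]^2 + uz[kk]^2)
          ux[kk] <- ux[kk] / nrm; uy[kk] <- uy[kk] / nrm
          uz[kk] <- uz[kk] / nrm
          lay[kk] <- ifelse(gk, lay[kk] - 1L, lay[kk] + 1L)
          z[kk] <- ifelse(gk, zb[lay[kk] + 1] - 1e-12, zb[lay[kk]] + 1e-12)
        }
      }
    }
  }
  list(specular = rsp,
       reflected = sum(refl_w) / N,
       transmitted = sum(trans_w) / N,
       se_reflected = stats::sd(refl_w) / sqrt(N),
       se_transmitted = stats::sd(trans_w) / sqrt(N))
}

# --- exact NNLS by support enumeration ------------------------------------
# Enumerates every subset of columns, solves the unconstrained LS on the
# subset via QR, keeps feasible candidates and returns the best; exact for
# small column counts.
oracle_nnls <- function(X, b) {
  p <- ncol(X)
  subsets <- unlist(lapply(seq_len(p), function(k)
    utils::combn(p, k, simplify = FALSE)), recursive = FALSE)
  best <- rep(0, p)
  best_rss <- sum(b^2)
  for (sel in subsets) {
    beta <- tryCatch(qr.coef(qr(X[, sel, drop = FALSE]), b),
                     error = function(e) NULL)
    if (is.null(beta) || any(is.na(beta)) || any(beta < -1e-12)) next
    r <- b - X[, sel, drop = FALSE] %*% pmax(beta, 0)
    rss <- sum(r^2)
    if (rss < best_rss - 1e-10) {
      best_rss <- rss
      best <- rep(0, p); best[sel] <- pmax(beta, 0)
    }
  }
  best
}

# --- 1-D grid scan over SO2 -----------------------------------------------
# For each candidate saturation, the model is linear in (offset, scale);
# returns the saturation minimizing the residual sum of squares.
oracle_so2_scan <- function(A, grid = wavelength_grid(),
                            candidates = seq(0, 1, by = 1e-4)) {
  eps <- extinction_at(grid)
  rss <- vapply(candidates, function(s) {
    v <- eps$eps_oxy * s + eps$eps_deoxy * (1 - s)
    fit <- stats::lm.fit(cbind(1, v), A)
    sum(fit$residuals^2)
  }, 0)
  candidates[which.min(rss)]
}
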