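# Independent oracles used across tests. These deliberately avoid the
# package's own code paths: plain arithmetic, lm(), and EBImage labeling.

# The packaged reference table, for tests that freeze expected values.
table1 <- function() pef_sample_table()

table1_train <- function() {
  tab <- table1()
  tab[tab$role == "train", , drop = FALSE]
}

# Ordinary least squares predictions (closed form via lm).
ols_oracle <- function(train, newdata,
                       predictors = c("yp_rate", "pi_rate"),
                       response = "fusion_rate") {
  fm <- stats::as.formula(paste(response, "~",
                                paste(predictors, collapse = "+")))
  unname(stats::predict(stats::lm(fm, data = train), newdata = newdata))
}

# One-component PLS1 prediction by the closed form
# w = X'y/||X'y||, t = Xw, c = t'y/t't, written with plain arithmetic.
pls1_closed_form <- function(train, newdata,
                             predictors = c("yp_rate", "pi_rate"),
                             response = "fusion_rate") {
  X <- as.matrix(train[, predictors])
  y <- train[[response]]
  mx <- colMeans(X); sx <- apply(X, 2, sd)
  Xs <- sweep(sweep(X, 2, mx), 2, sx, "/")
  ys <- (y - mean(y)) / sd(y)
  w <- drop(t(Xs) %*% ys); w <- w / sqrt(sum(w^2))
  tv <- drop(Xs %*% w)
  cc <- sum(tv * ys) / sum(tv^2)
  Xn <- sweep(sweep(as.matrix(newdata[, predictors]), 2, mx), 2, sx, "/")
  unname(mean(y) + sd(y) * cc * drop(Xn %*% w))
}

# Brute-force leave-one-out Q2 of the one-component model, written as an
# explicit fold loop over the closed form above.
loo_q2_oracle <- function(tab, predictors = c("yp_rate", "pi_rate"),
                          response = "fusion_rate") {
  y <- tab[[response]]
  press <- 0
  for (i in seq_len(nrow(tab))) {
    pred <- pls1_closed_form(tab[-i, ], tab[i, , drop = FALSE],
                             predictors, response)
    press <- press + (y[i] - pred)^2
  }
  1 - press / sum((y - mean(y))^2)
}

# Periodic connected-component count by non-periodic labeling of a 2x2
# tiled occupancy grid (EBImage) plus union-find over original cells.
periodic_pore_count_oracle <- function(frame, bounds, cell_size,
                                       slab_fraction = 0.5,
                                       min_cells = 2L) {
  mid <- mean(bounds); half <- diff(bounds) * slab_fraction / 2
  keep <- frame$labels == "WATER" &
    frame$positions[, 3] > mid - half & frame$positions[, 3] < mid + half
  x <- frame$positions[keep, 1]; y <- frame$positions[keep, 2]
  Lx <- frame$box[1]; Ly <- frame$box[2]
  nx <- max(1L, round(Lx / cell_size)); ny <- max(1L, round(Ly / cell_size))
  occ <- matrix(FALSE, nx, ny)
  occ[cbind(pmin(floor(x / (Lx / nx)) + 1, nx),
            pmin(floor(y / (Ly / ny)) + 1, ny))] <- TRUE
  big <- rbind(cbind(occ, occ), cbind(occ, occ))
  lab <- EBImage::bwlabel(big)
  parent <- seq_len(nx * ny)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (lv in setdiff(unique(as.integer(lab)), 0L)) {
    cells <- which(lab == lv, arr.ind = TRUE)
    orig <- unique(as.integer((cells[, 1] - 1L) %% nx +
                                nx * ((cells[, 2] - 1L) %% ny) + 1L))
    if (length(orig) > 1) {
      r1 <- find(orig[1])
      for (k in 2:length(orig)) {
        rk <- find(orig[k])
        if (rk != r1) parent[rk] <- r1
      }
    }
  }
  roots <- vapply(which(occ), find, integer(1))
  sizes <- table(roots)
  sum(sizes >= min_cells)
}

# A noiseless table whose response is an exact linear function of the
# predictors; the quadratic second column is exactly orthogonal to the
# (centered) linear first column by symmetry.
linear_table <- function(n = 12) {
  x1 <- seq_len(n)
  yp <- 40 + 2 * x1
  pi_ <- 50 + 0.4 * (x1 - (n + 1) / 2)^2
  data.frame(sample_id = sprintf("s%02d", seq_len(n)),
             pulse_width_ns = 200, field_strength_kv_cm = 1,
             yp_rate = yp, pi_rate = pi_,
             fusion_rate = 0.05 * yp + 0.1 * pi_,
             role = "unassigned", stringsAsFactors = FALSE)
}
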