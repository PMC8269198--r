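# The convolution engine is verified against direct computation and by
# finite differences; these checks gate everything the models module does.

test_that("conv2d forward matches a direct loop computation", {
  set.seed(91)
  H <- 7; W <- 6; Cin <- 3; Cout <- 2; k <- 3
  x <- array(rnorm(H * W * Cin), c(H, W, Cin, 1))
  w <- array(rnorm(k * k * Cin * Cout), c(k, k, Cin, Cout))
  b <- rnorm(Cout)
  for (stride in 1:2) for (dil in 1:2) {
    pad <- dil  # 'same'-ish
    y <- tamseg:::.cpp_conv2d_fwd(x, w, b, stride, pad, dil, 1L)
    Ho <- dim(y)[1]; Wo <- dim(y)[2]
    # direct evaluation at a handful of positions
    for (trial in 1:8) {
      ho <- sample(Ho, 1); wo <- sample(Wo, 1); co <- sample(Cout, 1)
      acc <- b[co]
      for (kh in 1:k) for (kw in 1:k) for (c in 1:Cin) {
        hi <- (ho - 1) * stride - pad + (kh - 1) * dil + 1
        wi <- (wo - 1) * stride - pad + (kw - 1) * dil + 1
        if (hi >= 1 && hi <= H && wi >= 1 && wi <= W)
          acc <- acc + x[hi, wi, c, 1] * w[kh, kw, c, co]
      }
      expect_equal(y[ho, wo, co, 1], acc, tolerance = 1e-12)
    }
  }
})

test_that("grouped (depthwise) convolution keeps channels independent", {
  set.seed(92)
  x <- array(rnorm(6 * 6 * 4), c(6, 6, 4, 1))
  w <- array(rnorm(3 * 3 * 1 * 4), c(3, 3, 1, 4))
  y <- tamseg:::.cpp_conv2d_fwd(x, w, numeric(4), 1L, 1L, 1L, 4L)
  # channel c of the output only depends on channel c of the input
  x2 <- x; x2[, , 2, ] <- 0
  y2 <- tamseg:::.cpp_conv2d_fwd(x2, w, numeric(4), 1L, 1L, 1L, 4L)
  expect_equal(y[, , -2, ], y2[, , -2, ])
  expect_false(isTRUE(all.equal(y[, , 2, ], y2[, , 2, ])))
})

test_that("conv2d backward matches finite differences", {
  set.seed(93)
  x <- array(rnorm(6 * 5 * 2), c(6, 5, 2, 1))
  w <- array(rnorm(3 * 3 * 2 * 3), c(3, 3, 2, 3))
  b <- rnorm(3)
  dy <- array(rnorm(6 * 5 * 3), c(6, 5, 3, 1))
  g <- tamseg:::.cpp_conv2d_bwd(x, w, dy, 1L, 1L, 1L, 1L)
  loss <- function(x_, w_, b_) sum(tamseg:::.cpp_conv2d_fwd(x_, w_, b_, 1L, 1L, 1L, 1L) * dy)
  eps <- 1e-6
  for (j in sample(length(w), 5)) {
    wp <- w; wp[j] <- wp[j] + eps
    wm <- w; wm[j] <- wm[j] - eps
    expect_equal(g$dw[j], (loss(x, wp, b) - loss(x, wm, b)) / (2 * eps), tolerance = 1e-5)
  }
  for (j in sample(length(x), 5)) {
    xp <- x; xp[j] <- xp[j] + eps
    xm <- x; xm[j] <- xm[j] - eps
    expect_equal(g$dx[j], (loss(xp, w, b) - loss(xm, w, b)) / (2 * eps), tolerance = 1e-5)
  }
  expect_equal(as.numeric(g$db), apply(dy, 3, sum), tolerance = 1e-10)
})

test_that("maxpool/unpool round-trip preserves argmax positions", {
  set.seed(94)
  # positive values: re-pooling an unpooled field must then reproduce the
  # pooled maxima exactly (zero fill never wins a window)
  x <- array(runif(8 * 8 * 2, 0.1, 1), c(8, 8, 2, 1))
  r <- tamseg:::.cpp_maxpool2_fwd(x)
  expect_equal(r$y[1, 1, 1, 1], max(x[1:2, 1:2, 1, 1]))
  up <- tamseg:::.cpp_maxunpool2_fwd(r$y, r$idx, 8L, 8L)
  # unpooled values sit exactly at the argmax positions
  pooled_again <- tamseg:::.cpp_maxpool2_fwd(up)
  expect_equal(pooled_again$y, r$y)
  expect_equal(sum(up != 0), sum(r$y != 0))
})

test_that("bilinear upsampling backward is the exact adjoint", {
  set.seed(95)
  x <- array(rnorm(5 * 4 * 2), c(5, 4, 2, 1))
  dy <- array(rnorm(10 * 8 * 2), c(10, 8, 2, 1))
  y <- tamseg:::.cpp_upsample_bilinear_fwd(x, 10L, 8L)
  dx <- tamseg:::.cpp_upsample_bilinear_bwd(dy, 5L, 4L)
  # <Ax, dy> == <x, A^T dy> for the linear operator A
  expect_equal(sum(y * dy), sum(x * dx), tolerance = 1e-10)
  # constant fields are preserved exactly
  const <- array(3, c(5, 4, 1, 1))
  expect_equal(as.numeric(tamseg:::.cpp_upsample_bilinear_fwd(const, 15L, 12L)),
               rep(3, 15 * 12))
})

test_that("8-connected labeling agrees with a recursive flood fill", {
  flood_label <- function(mask) {
    lab <- matrix(0L, nrow(mask), ncol(mask))
    cur <- 0L
    for (j in seq_len(ncol(mask))) for (i in seq_len(nrow(mask))) {
      if (mask[i, j] && lab[i, j] == 0L) {
        cur <- cur + 1L
        stack <- list(c(i, j))
        while (length(stack)) {
          p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
          if (p[1] < 1 || p[1] > nrow(mask) || p[2] < 1 || p[2] > ncol(mask)) next
          if (!mask[p[1], p[2]] || lab[p[1], p[2]] != 0L) next
          lab[p[1], p[2]] <- cur
          for (dy in -1:1) for (dx in -1:1)
            if (dy || dx) stack[[length(stack) + 1L]] <- c(p[1] + dy, p[2] + dx)
        }
      }
    }
    lab
  }
  set.seed(96)
  for (trial in 1:5) {
    mask <- matrix(runif(20 * 20) > 0.6, 20, 20)
    fast <- tamseg:::.cpp_label_components(mask)
    slow <- flood_label(mask)
    # same partition (possibly different id order)
    expect_identical(sbd(label_mask(fast, canonical = FALSE),
                         label_mask(slow, canonical = FALSE)),
                     if (any(mask)) 1 else 1)
    expect_identical(max(fast), max(slow))
  }
})

test_that("mean shift finds well-separated modes and assigns all points", {
  set.seed(97)
  X <- rbind(matrix(rnorm(100, 0, 0.05), 50, 2),
             sweep(matrix(rnorm(100, 0, 0.05), 50, 2), 2, c(5, 5), "+"))
  r <- tamseg:::.cpp_mean_shift(X, seq_len(nrow(X)), 0.5, 100L, 1e-4)
  expect_identical(r$k, 2L)
  expect_identical(sort(unique(r$assignment)), 1:2)
  expect_identical(length(unique(r$assignment[1:50])), 1L)
  expect_identical(length(unique(r$assignment[51:100])), 1L)
  expect_equal(sort(r$modes[, 1]), c(0, 5), tolerance = 0.1)
})

test_that("adam with the lr schedule reduces a small regression loss", {
  set.seed(98)
  net <- tamseg:::nn_new()
  input <- tamseg:::nn_add(net, "input")
  c1 <- tamseg:::nn_relu(net, tamseg:::nn_conv(net, input, 1L, 4L))
  head <- tamseg:::nn_conv(net, c1, 4L, 1L, k = 1L)
  x <- array(rnorm(8 * 8), c(8, 8, 1, 1))
  target <- array(sin(outer(1:8, 1:8) / 4), c(8, 8, 1, 1))
  opt <- tamseg:::adam_new(net, lr = 0.02)
  losses <- numeric(150)
  for (it in 1:150) {
    fwd <- tamseg:::nn_forward(net, x)
    d <- fwd$vals[[head]] - target
    losses[it] <- mean(d^2)
    g <- stats::setNames(list(2 * d / length(d)), as.character(head))
    tamseg:::nn_backward(net, fwd, g)
    tamseg:::adam_step(opt)
  }
  expect_lt(losses[150], 0.4 * losses[1])
})
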