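# Structure and behaviour of the nested dense-skip network: node graph
# enumeration, shape preservation, determinism and gradient flow.

test_that("node graph matches the dense-skip recurrence for depths 2-5", {
  for (d in 2:5) {
    cfg <- unetpp_config(depth = d, base_channels = 2)
    m <- build_unetpp(cfg)
    expect_equal(nrow(m$nodes), d * (d + 1) / 2)
    for (r in seq_len(nrow(m$nodes))) {
      i <- m$nodes$i[r]; j <- m$nodes$j[r]
      expect_lte(i + j, d - 1)
      expect_equal(m$nodes$n_inputs[r], if (j == 0) 1L else j + 1L)
    }
  }
  # depth 4: X^{0,3} concatenates X^{0,0..2} plus the up-sampled X^{1,2}
  m4 <- build_unetpp(unetpp_config(depth = 4, base_channels = 2))
  n03 <- m4$nodes[m4$nodes$i == 0 & m4$nodes$j == 3, ]
  expect_equal(n03$n_inputs, 4L)
  expect_equal(n03$in_ch, 4L * 2L)    # four inputs at top-level width
  # depth 2 smallest instance: X^{0,0}, X^{1,0}, X^{0,1}
  m2 <- build_unetpp(unetpp_config(depth = 2, base_channels = 2))
  expect_setequal(m2$nodes$key, c("x0_0", "x1_0", "x0_1"))
})

test_that("output lattice equals input lattice and stays in [0,1]", {
  m <- build_unetpp(unetpp_config(depth = 3, base_channels = 4))
  x <- matrix(runif(96 * 96), 96)
  p <- unetpp_predict(m, x)
  expect_equal(dim(p), c(96L, 96L, 1L, 1L))
  expect_true(all(p >= 0 & p <= 1))
  m5 <- build_unetpp(unetpp_config(depth = 5, base_channels = 2))
  p5 <- unetpp_predict(m5, array(runif(32 * 48 * 2), c(32, 48, 1, 2)))
  expect_equal(dim(p5), c(32L, 48L, 1L, 2L))
})

test_that("desk-scale model stays small and forward is deterministic", {
  m <- build_unetpp(unetpp_config(depth = 3, base_channels = 8))
  expect_lt(n_parameters(m), 5e5)
  x <- array(runif(32 * 32 * 2), c(32, 32, 1, 2))
  expect_identical(unetpp_predict(m, x), unetpp_predict(m, x))
  # same seed, rebuilt model: identical weights
  m2 <- build_unetpp(unetpp_config(depth = 3, base_channels = 8))
  expect_identical(m$params, m2$params)
  # the model is not constant in its input
  x2 <- x; x2[5, 5, 1, 1] <- x2[5, 5, 1, 1] + 1
  expect_false(identical(unetpp_predict(m, x), unetpp_predict(m, x2)))
})

test_that("a zeroed prediction head outputs probability one half", {
  m <- build_unetpp(unetpp_config(depth = 2, base_channels = 4))
  m$params[["head1.w"]][] <- 0
  m$params[["head1.b"]][] <- 0
  p <- unetpp_predict(m, matrix(runif(16 * 16), 16))
  expect_true(all(p == 0.5))
})

test_that("invalid configurations fail with the offending field named", {
  expect_error(unetpp_config(depth = 1), "depth")
  expect_error(unetpp_config(base_channels = 0), "base_channels")
  expect_error(build_unetpp(unetpp_config(encoder = "nonexistent")),
               "encoder")
  m <- build_unetpp(unetpp_config(depth = 3))
  expect_error(unetpp_predict(m, matrix(0, 30, 30)), "divisible")
})

test_that("gradient reaches every parameter tensor after one step", {
  set.seed(404)
  for (d in 2:4) {
    m <- build_unetpp(unetpp_config(depth = d, base_channels = 2, seed = d))
    x <- array(runif(16 * 16 * 2), c(16, 16, 1, 2))
    y <- array(0, c(16, 16, 1, 2)); y[5:10, 7:9, , ] <- 1
    fw <- ettseg:::unetpp_forward_full(m, x, train = TRUE)
    h <- as.character(d - 1)
    vg <- ettseg:::loss_value_grad(parse_loss("bce-dice"), fw$logits[[h]], y)
    g <- ettseg:::unetpp_backward(m, fw, setNames(list(vg$grad), h))
    expect_setequal(names(g), names(m$params))
    nz <- vapply(g, function(t) any(t != 0), logical(1))
    expect_true(all(nz), label = paste("depth", d, "all tensors touched"))
  }
})

test_that("deep supervision attaches heads to every top-row node", {
  m <- build_unetpp(unetpp_config(depth = 4, base_channels = 2,
                                  deep_supervision = TRUE))
  expect_true(all(paste0("head", 1:3, ".w") %in% names(m$params)))
  fw <- ettseg:::unetpp_forward_full(m, array(runif(16 * 16), c(16, 16, 1, 1)),
                                     train = TRUE)
  expect_setequal(names(fw$logits), c("1", "2", "3"))
  # inference still reads only the final head
  p <- unetpp_predict(m, matrix(runif(16 * 16), 16))
  expect_equal(dim(p)[1:2], c(16L, 16L))
})

test_that("checkpoints reload as self-describing models", {
  m <- build_unetpp(unetpp_config(depth = 3, base_channels = 4, seed = 9))
  x <- matrix(runif(32 * 32), 32)
  ck <- tempfile(fileext = ".rds")
  save_checkpoint(m, ck)
  m2 <- load_checkpoint(ck)
  expect_identical(unetpp_predict(m, x), unetpp_predict(m2, x))
  expect_equal(m2$config$depth, 3L)
  unlink(ck)
})

test_that("registered encoders replace the backbone column", {
  single_conv_encoder <- function(config) {
    list(
      init = function(cin, cout) {
        list(w = array(runif(9 * cin * cout, -0.3, 0.3),
                       c(3, 3, cin, cout)),
             b = runif(cout, -0.1, 0.1))
      },
      forward = function(x, params, train) {
        h <- ettseg:::cpp_conv2d_forward(x, params$w, params$b, 1L)
        list(y = h * (h > 0), cache = list(x = x, mask = h > 0))
      },
      backward = function(dy, params, cache) {
        dy <- dy * cache$mask
        cb <- ettseg:::cpp_conv2d_backward(cache$x, params$w, dy, 1L)
        list(dx = cb$dx, grads = list(w = cb$dw, b = cb$db))
      })
  }
  register_encoder("single_conv", single_conv_encoder)
  m <- build_unetpp(unetpp_config(depth = 3, base_channels = 4,
                                  encoder = "single_conv", seed = 6))
  # backbone nodes now hold the custom block's parameters
  expect_true("x1_0.w" %in% names(m$params))
  expect_false("x1_0.conv2.w" %in% names(m$params))
  # decoder nodes keep the standard double-conv block
  expect_true("x0_1.conv2.w" %in% names(m$params))
  x <- array(runif(32 * 32 * 2), c(32, 32, 1, 2))
  p <- unetpp_predict(m, x)
  expect_equal(dim(p), c(32L, 32L, 1L, 2L))
  # gradients flow through the custom encoder
  y <- array(0, c(32, 32, 1, 2)); y[10:20, 15:17, , ] <- 1
  fw <- ettseg:::unetpp_forward_full(m, x, train = TRUE)
  vg <- ettseg:::loss_value_grad(parse_loss("dice"), fw$logits[["2"]], y)
  g <- ettseg:::unetpp_backward(m, fw, list("2" = vg$grad))
  expect_setequal(names(g), names(m$params))
  expect_true(any(g[["x2_0.w"]] != 0))
})
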