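# A hand-built two-layer model with a known single activation source, used
# to pin Grad-CAM++ localization: the tap has one channel whose only active
# cell is at a chosen location, and the output depends on that channel alone.
toy_single_source_model <- function(h = 16L, w = 16L, cell = c(5L, 9L),
                                    gain = 8) {
  force(h); force(w); force(gain)
  net <- new.env(parent = emptyenv())
  net$params <- list()
  net$bn <- list()
  sel <- matrix(0, h * w, 1)
  sel[(cell[1] - 1L) * w + cell[2], 1] <- 1  # engine layout: row i*W + j
  net$forward <- function(xmat, training = FALSE, collect = FALSE) {
    x <- cervseg:::ad_const(xmat)
    # tap: channel = gray intensity masked to the single cell
    wsel <- cervseg:::ad_param(matrix(1 / 3, 3, 1))
    tap0 <- cervseg:::ad_conv(x, wsel, NULL, k = 1L)
    gate <- cervseg:::new_node(sel * gain)
    tap <- cervseg:::ad_relu(
      cervseg:::new_node(cervseg:::tmeta(tap0$value * sel * gain, 1L, h, w),
                         list(tap0),
                         backfn = function(dy) list(
                           cervseg:::tmeta(dy * sel * gain, 1L, h, w))))
    wout <- cervseg:::ad_param(matrix(1, 1, 1))
    out <- cervseg:::ad_sigmoid(cervseg:::ad_conv(tap, wout, NULL, k = 1L))
    res <- list(out = out)
    if (collect) {
      res$resnet_taps <- list(NULL, NULL, NULL, tap)
      res$fused <- res$resnet_taps
      res$aspp <- tap
      res$decoder <- list(out, out, out, out)
    }
    res
  }
  new("SegModel", config = tiny_model_config(), engine = net)
}
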