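# Shared fixtures, rendered once per test run and memoised.

.fx <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fx[[name]])) .fx[[name]] <- build()
  .fx[[name]]
}

# noise-free fronto-parallel render of the 12.57 cm^2 circular defect model
fxRender90 <- function() fixture("r90", function()
  renderScene(sceneSpec(), captureConfig(30, 90)))

# oblique capture of the same scene
fxRender60 <- function() fixture("r60", function()
  renderScene(sceneSpec(), captureConfig(40, 60)))

fxDetect90 <- function() fixture("d90", function() detectPatch(fxRender90()))
fxDetect60 <- function() fixture("d60", function() detectPatch(fxRender60()))

fxRect90 <- function() fixture("rect90", function()
  rectifyImage(fxRender90(), fxDetect90(), targetPxPerCm = 25))

# synthetic disk image (dark on light), for edge-map / GVF / snake checks
fxDisk <- function() fixture("disk", function() {
  h <- 120; w <- 120; R <- 30; cx <- 60; cy <- 60
  xx <- matrix(rep(0:(w - 1), each = h), h, w)
  yy <- matrix(rep(0:(h - 1), w), h, w)
  img <- array(0.8, c(h, w, 3))
  dm <- (xx - cx)^2 + (yy - cy)^2 <= R^2
  for (ch in 1:3) { m <- img[, , ch]; m[dm] <- 0.2; img[, , ch] <- m }
  list(img = img, mask = dm, R = R, cx = cx, cy = cy)
})

fxDiskGVF <- function() fixture("diskGVF", function()
  computeGVF(computeEdgeMap(fxDisk()$img, sigma = 1), gvfParams()))
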