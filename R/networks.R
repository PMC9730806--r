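#' Per-voxel deformation field
#'
#' Displacements are in voxel units: the warper samples the moving image at
#' `x + df(x)` on the voxel grid, so for anisotropic data a displacement of
#' one unit along axis `a` corresponds to `spacing[a]` millimetres.
#' Component order matches the spatial array axis order.
#'
#' @param displacements 4D array (3 spatial dims x 3 components), finite.
#' @param spacing voxel spacing of the follow-up grid, mm.
#' @return An object of class `deformation_field`.
#' @export
deformation_field <- function(displacements, spacing = c(1, 1, 1)) {
  displacements <- as.array(displacements)
  d <- dim(displacements)
  if (length(d) != 4L || d[4] != 3L)
    stop("deformation_field: displacements must be a 4D array with last dimension 3")
  if (!all(is.finite(displacements)))
    stop("deformation_field: displacements contain non-finite values")
  structure(list(displacements = displacements, spacing = as.numeric(spacing)),
            class = "deformation_field")
}

#' @export
print.deformation_field <- function(x, ...) {
  cat("<deformation_field> ", paste(dim(x$displacements)[1:3], collapse = " x "),
      " voxels, max |u| = ", signif(max(abs(x$displacements)), 4),
      " vox\n", sep = "")
  invisible(x)
}

#' Network architecture configuration
#'
#' Both cascade stages use the same architecture: a registration U-Net that
#' maps the (baseline, follow-up) pair to a dense deformation field, a
#' differentiable warper, and a two-branch segmentation U-Net whose branches
#' see the image pair and the deformation field and whose outputs are
#' concatenated before a 1x1x1 logistic classification layer.  Each U-Net
#' has four downsampling and four upsampling steps built from core blocks of
#' two 3x3x3 stride-1 convolutions; registration-path activations are leaky
#' (so displacements can be negative), segmentation-path activations are
#' plain rectifiers.
#'
#' @param base_channels channels of the four contracting-path levels
#'   (default 64, 128, 256, 512); the expansive path mirrors them in
#'   reverse.
#' @param kernel_size odd convolution kernel size (default 3).
#' @param leaky_slope negative-part slope for registration-path activations.
#' @param df_source `"learned"` (registration U-Net trained end-to-end),
#'   `"external"` (precomputed deformation field supplied as input), or
#'   `"none"` (no deformation field; the second segmentation branch is
#'   disabled).
#' @param patch_shape 3D patch size; each axis must be divisible by 16
#'   (four 2x poolings).
#' @param input_center,input_scale affine transform
#'   `(x - input_center) * input_scale` applied to the (standardized) image
#'   intensities before they enter the networks and the similarity loss.
#'   The defaults (0, 0.01) map the 0-100 standard intensity scale to unit
#'   range.  (A zero-centred variant starves the narrow rectifier layers
#'   used in reduced test networks, so the offset is kept.)
#' @param use_registration_branch logical; derived from `df_source` when
#'   omitted.
#' @return An object of class `network_config`.
#' @export
network_config <- function(base_channels = c(64, 128, 256, 512),
                           kernel_size = 3, leaky_slope = 0.2,
                           df_source = c("learned", "external", "none"),
                           patch_shape = c(32, 32, 32), input_center = 0,
                           input_scale = 0.01,
                           use_registration_branch = NULL) {
  df_source <- match.arg(df_source)
  base_channels <- as.integer(base_channels)
  if (length(base_channels) != 4L || any(base_channels <= 0))
    stop("configuration error: base_channels must be 4 positive integers")
  if (kernel_size %% 2 != 1 || kernel_size < 1)
    stop("configuration error: kernel_size must be odd and positive")
  if (leaky_slope <= 0 || leaky_slope >= 1)
    stop("configuration error: leaky_slope must lie in (0, 1)")
  patch_shape <- as.integer(patch_shape)
  if (length(patch_shape) != 3L || any(patch_shape %% 16L != 0L) ||
      any(patch_shape <= 0L))
    stop("configuration error: patch_shape must be divisible by 16 on every axis")
  if (is.null(use_registration_branch))
    use_registration_branch <- df_source == "learned"
  stopifnot(input_scale > 0)
  structure(list(base_channels = base_channels,
                 kernel_size = as.integer(kernel_size),
                 leaky_slope = leaky_slope, df_source = df_source,
                 patch_shape = patch_shape, input_center = input_center,
                 input_scale = input_scale,
                 use_registration_branch = use_registration_branch),
            class = "network_config")
}

## ---- parameter initialization -------------------------------------------

init_conv <- function(cin, cout, k) {
  fan_in <- k^3 * cin
  list(W = matrix(stats::rnorm(fan_in * cout, sd = sqrt(2 / fan_in)),
                  fan_in, cout),
       b = numeric(cout), k = as.integer(k))
}

init_conv1 <- function(cin, cout) {
  list(W = matrix(stats::rnorm(cin * cout, sd = sqrt(2 / cin)), cin, cout),
       b = numeric(cout))
}

unet_init <- function(in_ch, ch, k) {
  block <- function(cin, cout)
    list(c1 = init_conv(cin, cout, k), c2 = init_conv(cout, cout, k))
  list(enc1 = block(in_ch, ch[1]), enc2 = block(ch[1], ch[2]),
       enc3 = block(ch[2], ch[3]), enc4 = block(ch[3], ch[4]),
       bott = block(ch[4], ch[4]),
       dec4 = block(2L * ch[4], ch[4]), dec3 = block(ch[4] + ch[3], ch[3]),
       dec2 = block(ch[3] + ch[2], ch[2]), dec1 = block(ch[2] + ch[1], ch[1]))
}

#' Number of trainable parameters
#'
#' @param x a network object or parameter list.
#' @return Integer parameter count.
#' @export
n_params <- function(x) {
  if (is.list(x)) {
    if (!is.null(x$params)) return(n_params(x$params))
    sum(vapply(names(x), function(nm) {
      if (nm == "k" || nm == "cfg") 0 else n_params(x[[nm]])
    }, numeric(1)))
  } else {
    length(x)
  }
}

## ---- forward / backward primitives --------------------------------------

act_fwd <- function(z, slope) .act_forward(z, slope)

act_bwd <- function(g, z, slope) .act_backward(g, z, slope)

conv_fwd <- function(x, layer) .conv3d_forward(x, dim(x), layer$W, layer$b, layer$k)

abind4 <- function(a, b) {
  da <- dim(a); db <- dim(b)
  array(c(a, b), c(da[1:3], da[4] + db[4]))
}

conv1_fwd <- function(x, layer) {
  d <- dim(x)
  y <- matrix(x, ncol = d[4]) %*% layer$W
  y <- sweep(y, 2, layer$b, `+`)
  array(y, c(d[1:3], ncol(layer$W)))
}

conv1_bwd <- function(x, layer, gy) {
  d <- dim(x)
  gm <- matrix(gy, ncol = ncol(layer$W))
  xm <- matrix(x, ncol = d[4])
  list(gx = array(gm %*% t(layer$W), d),
       grads = list(W = crossprod(xm, gm), b = colSums(gm)))
}

block_fwd <- function(x, blk, slope, keep = TRUE) {
  if (!keep) {
    a1 <- act_fwd(conv_fwd(x, blk$c1), slope)
    return(list(out = act_fwd(conv_fwd(a1, blk$c2), slope), cache = NULL))
  }
  f1 <- .conv3d_forward_cached(x, dim(x), blk$c1$W, blk$c1$b, blk$c1$k)
  a1 <- act_fwd(f1$y, slope)
  f2 <- .conv3d_forward_cached(a1, dim(a1), blk$c2$W, blk$c2$b, blk$c2$k)
  a2 <- act_fwd(f2$y, slope)
  list(out = a2, cache = list(x = x, z1 = f1$y, M1 = f1$M, a1 = a1,
                              z2 = f2$y, M2 = f2$M))
}

block_bwd <- function(blk, cache, g, slope) {
  g2 <- act_bwd(g, cache$z2, slope)
  b2 <- .conv3d_backward(cache$a1, dim(cache$a1), blk$c2$W, g2, blk$c2$k,
                         cache$M2)
  g1 <- act_bwd(b2$gx, cache$z1, slope)
  b1 <- .conv3d_backward(cache$x, dim(cache$x), blk$c1$W, g1, blk$c1$k,
                         cache$M1)
  list(gx = b1$gx,
       grads = list(c1 = list(W = b1$gw, b = b1$gb),
                    c2 = list(W = b2$gw, b = b2$gb)))
}

unet_fwd <- function(net, x, slope, keep = TRUE) {
  skips <- ec <- pidx <- pdims <- vector("list", 4)
  h <- x
  for (l in 1:4) {
    bf <- block_fwd(h, net[[paste0("enc", l)]], slope, keep)
    skips[[l]] <- bf$out; ec[[l]] <- bf$cache; pdims[[l]] <- dim(bf$out)
    pl <- .maxpool3d_forward(bf$out, dim(bf$out))
    pidx[[l]] <- pl$idx; h <- pl$y
  }
  bo <- block_fwd(h, net$bott, slope, keep)
  h <- bo$out
  dc <- catdims <- vector("list", 4)
  for (l in 4:1) {
    up <- .upsample3d_forward(h, dim(h))
    cc <- abind4(up, skips[[l]])
    catdims[[l]] <- c(dim(up)[4], dim(skips[[l]])[4])
    bf <- block_fwd(cc, net[[paste0("dec", l)]], slope, keep)
    dc[[l]] <- bf$cache; h <- bf$out
  }
  if (!keep) return(list(out = h, cache = NULL))
  list(out = h, cache = list(ec = ec, pidx = pidx, pdims = pdims,
                             bo = bo$cache, dc = dc, catdims = catdims))
}

unet_bwd <- function(net, cache, g, slope) {
  grads <- list()
  gskips <- vector("list", 4)
  for (l in 1:4) {
    bb <- block_bwd(net[[paste0("dec", l)]], cache$dc[[l]], g, slope)
    grads[[paste0("dec", l)]] <- bb$grads
    nup <- cache$catdims[[l]][1]
    nskip <- cache$catdims[[l]][2]
    gup <- bb$gx[, , , seq_len(nup), drop = FALSE]
    gskips[[l]] <- bb$gx[, , , nup + seq_len(nskip), drop = FALSE]
    g <- .upsample3d_backward(gup, as.integer(c(dim(gup)[1:3] / 2L, nup)))
  }
  bb <- block_bwd(net$bott, cache$bo, g, slope)
  grads$bott <- bb$grads
  g <- bb$gx
  for (l in 4:1) {
    gpool <- .maxpool3d_backward(cache$pidx[[l]], g,
                                 as.integer(cache$pdims[[l]]))
    bb <- block_bwd(net[[paste0("enc", l)]], cache$ec[[l]],
                    gpool + gskips[[l]], slope)
    grads[[paste0("enc", l)]] <- bb$grads
    g <- bb$gx
  }
  list(gx = g, grads = grads)
}

## ---- network builders ----------------------------------------------------

#' Build the registration U-Net
#'
#' Maps a 2-channel (baseline, follow-up) patch to a 3-channel dense
#' displacement patch of the same spatial shape.  All internal activations
#' are leaky rectifiers so displacements can take either sign; the final
#' 1x1x1 projection to three components is linear.
#'
#' @param cfg a [network_config()].
#' @param seed optional RNG seed for reproducible weight initialization.
#' @return An object of class `registration_net`.
#' @export
build_registration_net <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "network_config"))
  if (!is.null(seed)) set.seed(seed)
  params <- list(unet = unet_init(2L, cfg$base_channels, cfg$kernel_size),
                 head = init_conv1(cfg$base_channels[1], 3L))
  # flow head initialized near zero so training starts from the identity
  # transform (the usual choice for spatial-transformer registration)
  params$head$W <- params$head$W * 1e-3
  structure(list(cfg = cfg, params = params), class = "registration_net")
}

#' Run the registration network on a patch pair
#'
#' @param net a `registration_net`.
#' @param baseline,followup 3D patches with the configured patch shape.
#' @return 4D displacement array (voxel units).
#' @export
forward_registration <- function(net, baseline, followup) {
  x2 <- abind4(array(baseline, c(dim(baseline), 1L)),
               array(followup, c(dim(followup), 1L)))
  r <- unet_fwd(net$params$unet, x2, net$cfg$leaky_slope)
  conv1_fwd(r$out, net$params$head)
}

#' Build the two-branch segmentation network
#'
#' Branch 1 sees the 2-channel (baseline, follow-up) patch; branch 2 sees
#' the 3-channel deformation field and is omitted for `df_source = "none"`.
#' Activations are plain rectifiers; branch outputs are concatenated and a
#' 1x1x1 convolution with a logistic output yields the per-voxel new-lesion
#' probability.
#'
#' @inheritParams build_registration_net
#' @return An object of class `segmentation_net`.
#' @export
build_segmentation_net <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "network_config"))
  if (!is.null(seed)) set.seed(seed)
  ch <- cfg$base_channels
  params <- list(branch1 = unet_init(2L, ch, cfg$kernel_size))
  if (cfg$df_source != "none")
    params$branch2 <- unet_init(3L, ch, cfg$kernel_size)
  head_in <- if (cfg$df_source == "none") ch[1] else 2L * ch[1]
  params$head <- init_conv1(head_in, 1L)
  params$head$b[] <- -2.5  # near-prior logit, as in build_joint_model
  structure(list(cfg = cfg, params = params), class = "segmentation_net")
}

#' Run the segmentation network on a patch pair
#'
#' @param net a `segmentation_net`.
#' @param baseline,followup 3D patches.
#' @param df 4D deformation-field patch; required unless the network was
#'   configured with `df_source = "none"`.
#' @return 3D array of probabilities in \[0, 1\].
#' @export
forward_segmentation <- function(net, baseline, followup, df = NULL) {
  x2 <- abind4(array(baseline, c(dim(baseline), 1L)),
               array(followup, c(dim(followup), 1L)))
  s1 <- unet_fwd(net$params$branch1, x2, 0)
  feat <- s1$out
  if (!is.null(net$params$branch2)) {
    if (is.null(df))
      stop("forward_segmentation: this configuration requires a deformation-field input")
    s2 <- unet_fwd(net$params$branch2, df, 0)
    feat <- abind4(feat, s2$out)
  } else if (!is.null(df)) {
    stop("forward_segmentation: df_source = \"none\" accepts only the image pair")
  }
  z <- conv1_fwd(feat, net$params$head)
  array(1 / (1 + exp(-z)), dim(z)[1:3])
}

#' Build the end-to-end joint registration + segmentation model
#'
#' Composes the registration U-Net, the differentiable warper, and the
#' two-branch segmentation network into one model trained end-to-end:
#' gradients from the segmentation, similarity, and smoothness loss terms
#' all reach the registration weights.  With `df_source = "external"` the
#' registration subnet is absent and the deformation field is taken from the
#' input; with `"none"` the model reduces to the single-branch segmentation
#' network.
#'
#' @inheritParams build_registration_net
#' @return An object of class `joint_model`.
#' @export
build_joint_model <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "network_config"))
  if (!is.null(seed)) set.seed(seed)
  ch <- cfg$base_channels
  params <- list()
  if (cfg$df_source == "learned") {
    params$reg <- unet_init(2L, ch, cfg$kernel_size)
    params$reg_head <- init_conv1(ch[1], 3L)
    # flow head initialized near zero: training starts from the identity
    # transform, the standard stabilization for learned registration
    params$reg_head$W <- params$reg_head$W * 1e-3
  }
  params$seg1 <- unet_init(2L, ch, cfg$kernel_size)
  if (cfg$df_source != "none")
    params$seg2 <- unet_init(3L, ch, cfg$kernel_size)
  head_in <- if (cfg$df_source == "none") ch[1] else 2L * ch[1]
  params$seg_head <- init_conv1(head_in, 1L)
  # start the classifier near the background-prior logit: new-lesion voxels
  # are rare even inside lesion-centred patches, and this initialization
  # avoids wasting early epochs driving the output towards the prior
  params$seg_head$b[] <- -2.5
  structure(list(cfg = cfg, params = params), class = "joint_model")
}

#' Forward pass of the joint model on one patch
#'
#' @param model a `joint_model`.
#' @param baseline,followup 3D patches.
#' @param df_external 4D deformation-field patch for
#'   `df_source = "external"`.
#' @param with_cache keep intermediate activations for a backward pass.
#' @param need_moved compute the warped (moved) baseline; skipped during
#'   inference where only the probability is needed.
#' @return List with `prob` (3D probabilities), `df` (4D displacements or
#'   NULL), `moved` (3D warped baseline or NULL) and, if requested, `cache`.
#' @export
forward_joint <- function(model, baseline, followup, df_external = NULL,
                          with_cache = FALSE, need_moved = TRUE) {
  cfg <- model$cfg
  if (!all(dim(baseline) == dim(followup)))
    stop("forward_joint: baseline and followup patches differ in shape")
  baseline <- (baseline - cfg$input_center) * cfg$input_scale
  followup <- (followup - cfg$input_center) * cfg$input_scale
  x2 <- abind4(array(baseline, c(dim(baseline), 1L)),
               array(followup, c(dim(followup), 1L)))
  df <- NULL; rcache <- NULL; rout <- NULL
  if (cfg$df_source == "learned") {
    r <- unet_fwd(model$params$reg, x2, cfg$leaky_slope, keep = with_cache)
    rout <- r$out; rcache <- r$cache
    df <- conv1_fwd(rout, model$params$reg_head)
  } else if (cfg$df_source == "external") {
    if (is.null(df_external))
      stop("forward_joint: df_source = \"external\" requires a deformation-field patch")
    df <- df_external
  }
  moved <- if (!is.null(df) && need_moved)
    .warp3d_forward(baseline, df, dim(baseline))
  s1 <- unet_fwd(model$params$seg1, x2, 0, keep = with_cache)
  feat <- s1$out; s2 <- NULL
  if (!is.null(df)) {
    s2 <- unet_fwd(model$params$seg2, df, 0, keep = with_cache)
    feat <- abind4(feat, s2$out)
  }
  z <- conv1_fwd(feat, model$params$seg_head)
  prob <- array(1 / (1 + exp(-z)), dim(z)[1:3])
  out <- list(prob = prob, df = df, moved = moved)
  if (with_cache)
    out$cache <- list(x2 = x2, baseline = baseline, rcache = rcache,
                      rout = rout, s1 = s1, s2 = s2, feat = feat, z = z)
  out
}

# Backward pass of the joint model.  gz is dL/d(logit), gmoved is
# dL/d(moved baseline) from the similarity term, gdf_direct is dL/d(df)
# from the smoothness regularizer.  Returns parameter gradients mirroring
# model$params.
backward_joint <- function(model, fw, gz, gmoved = NULL, gdf_direct = NULL) {
  cfg <- model$cfg
  ca <- fw$cache
  grads <- list()
  gz4 <- array(gz, c(dim(gz), 1L))
  hb <- conv1_bwd(ca$feat, model$params$seg_head, gz4)
  grads$seg_head <- hb$grads
  ch1 <- dim(ca$s1$out)[4]
  gs1 <- hb$gx[, , , seq_len(ch1), drop = FALSE]
  b1 <- unet_bwd(model$params$seg1, ca$s1$cache, gs1, 0)
  grads$seg1 <- b1$grads
  gdf <- gdf_direct
  if (!is.null(ca$s2)) {
    gs2 <- hb$gx[, , , ch1 + seq_len(ch1), drop = FALSE]
    b2 <- unet_bwd(model$params$seg2, ca$s2$cache, gs2, 0)
    grads$seg2 <- b2$grads
    gdf <- if (is.null(gdf)) b2$gx else gdf + b2$gx
  }
  if (cfg$df_source == "learned") {
    if (!is.null(gmoved)) {
      wb <- .warp3d_backward(ca$baseline, fw$df, dim(ca$baseline), gmoved)
      gdf <- if (is.null(gdf)) wb$gdf else gdf + wb$gdf
    }
    rh <- conv1_bwd(ca$rout, model$params$reg_head, gdf)
    grads$reg_head <- rh$grads
    rb <- unet_bwd(model$params$reg, ca$rcache, rh$gx, cfg$leaky_slope)
    grads$reg <- rb$grads
  }
  grads
}

#' Warp an image by a deformation field
#'
#' The output voxel at `x` samples the input image at `x + df(x)` by
#' trilinear interpolation; sampling coordinates are clamped to the image
#' extent (clamp-to-edge border), which avoids injecting background zeros
#' into the similarity loss at patch borders.  The operation is
#' differentiable with respect to both the image and the field.
#'
#' @param image 3D array or `volume3d`.
#' @param df `deformation_field` or 4D displacement array (voxel units).
#' @return Same type as `image`.
#' @export
warp <- function(image, df) {
  u <- if (inherits(df, "deformation_field")) df$displacements else df
  x <- if (inherits(image, "volume3d")) image$data else image
  if (!all(dim(x) == dim(u)[1:3]))
    stop("warp: image and deformation field differ in spatial shape")
  out <- .warp3d_forward(x, u, dim(x))
  if (inherits(image, "volume3d"))
    volume3d(out, image$spacing, image$affine)
  else out
}

## ---- data-dependent initialization ---------------------------------------

# Layer-sequential unit-variance calibration: scale each convolution so its
# pre-activations have unit standard deviation on a probe input.  This
# removes the seed-to-seed spread in how well-conditioned the random init
# happens to be, which otherwise decides whether the classifier "takes off"
# within a small epoch budget.  Degenerate (all-zero) inputs leave a layer
# untouched.
calibrate_conv <- function(layer, x, slope) {
  z <- conv_fwd(x, layer)
  m <- mean(z)
  s <- stats::sd(z)
  if (is.finite(s) && s > 1e-6) {
    layer$W <- layer$W / s
    layer$b <- (layer$b - m) / s
    z <- (z - m) / s
  }
  list(layer = layer, out = act_fwd(z, slope))
}

calibrate_block <- function(blk, x, slope) {
  r1 <- calibrate_conv(blk$c1, x, slope)
  r2 <- calibrate_conv(blk$c2, r1$out, slope)
  blk$c1 <- r1$layer; blk$c2 <- r2$layer
  list(blk = blk, out = r2$out)
}

calibrate_unet <- function(net, x, slope) {
  skips <- vector("list", 4)
  h <- x
  for (l in 1:4) {
    r <- calibrate_block(net[[paste0("enc", l)]], h, slope)
    net[[paste0("enc", l)]] <- r$blk
    skips[[l]] <- r$out
    h <- .maxpool3d_forward(r$out, dim(r$out))$y
  }
  r <- calibrate_block(net$bott, h, slope)
  net$bott <- r$blk
  h <- r$out
  for (l in 4:1) {
    up <- .upsample3d_forward(h, dim(h))
    cc <- abind4(up, skips[[l]])
    r <- calibrate_block(net[[paste0("dec", l)]], cc, slope)
    net[[paste0("dec", l)]] <- r$blk
    h <- r$out
  }
  list(net = net, out = h)
}

# Calibrate all subnetworks of a joint model on one probe patch pair.  The
# flow head keeps its near-zero init (identity-transform start); the
# classifier head keeps its prior bias but its weights are scaled against
# the calibrated features.
calibrate_model <- function(model, baseline, followup, df_external = NULL) {
  cfg <- model$cfg
  baseline <- (baseline - cfg$input_center) * cfg$input_scale
  followup <- (followup - cfg$input_center) * cfg$input_scale
  x2 <- abind4(array(baseline, c(dim(baseline), 1L)),
               array(followup, c(dim(followup), 1L)))
  df <- NULL
  if (cfg$df_source == "learned") {
    r <- calibrate_unet(model$params$reg, x2, cfg$leaky_slope)
    model$params$reg <- r$net
    df <- conv1_fwd(r$out, model$params$reg_head)
  } else if (cfg$df_source == "external") {
    df <- df_external
  }
  r1 <- calibrate_unet(model$params$seg1, x2, 0)
  model$params$seg1 <- r1$net
  feat <- r1$out
  if (!is.null(df)) {
    r2 <- calibrate_unet(model$params$seg2, df, 0)
    model$params$seg2 <- r2$net
    feat <- abind4(feat, r2$out)
  }
  z <- conv1_fwd(feat, model$params$seg_head)
  s <- stats::sd(z - mean(z))
  if (is.finite(s) && s > 1e-6)
    model$params$seg_head$W <- model$params$seg_head$W / s
  model
}

## ---- optimizer helpers ----------------------------------------------------

zeros_like_params <- function(p) {
  if (is.list(p)) lapply(p, zeros_like_params) else p * 0
}

grad_add <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.list(a)) mapply(grad_add, a, b, SIMPLIFY = FALSE) else a + b
}

grad_scale <- function(g, s) {
  if (is.list(g)) lapply(g, grad_scale, s = s) else g * s
}

grad_sumsq <- function(g) {
  if (is.list(g)) sum(vapply(g, grad_sumsq, numeric(1))) else sum(g * g)
}

# One Adam update; `p`, `g`, `m`, `v` share structure.  The `k` (kernel
# size) leaves are bookkeeping, not parameters, and are skipped.
adam_step <- function(p, g, m, v, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  if (is.list(p)) {
    for (nm in names(p)) {
      if (nm == "k") next
      r <- adam_step(p[[nm]], g[[nm]], m[[nm]], v[[nm]], lr, t, beta1,
                     beta2, eps)
      p[[nm]] <- r$p; m[[nm]] <- r$m; v[[nm]] <- r$v
    }
    list(p = p, m = m, v = v)
  } else {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    list(p = p - lr * (m / (1 - beta1^t)) / (sqrt(v / (1 - beta2^t)) + eps),
         m = m, v = v)
  }
}

## ---- checkpoint serialization --------------------------------------------

params_to_json_list <- function(p) {
  if (is.list(p)) lapply(p, params_to_json_list)
  else if (is.matrix(p)) list(.mat = dim(p), v = as.numeric(p))
  else as.numeric(p)
}

params_from_json_list <- function(p) {
  if (is.list(p)) {
    if (!is.null(p$.mat)) matrix(as.numeric(p$v), p$.mat[1], p$.mat[2])
    else lapply(p, params_from_json_list)
  } else as.numeric(p)
}

#' Save / load a joint model as JSON (weights + configuration sidecar)
#'
#' @param model a `joint_model`.
#' @param path JSON file path.
#' @export
save_model <- function(model, path) {
  jsonlite::write_json(list(cfg = unclass(model$cfg),
                            params = params_to_json_list(model$params)),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(network_config, x$cfg[c("base_channels", "kernel_size",
                                         "leaky_slope", "df_source",
                                         "patch_shape", "input_center",
                                         "input_scale")])
  structure(list(cfg = cfg, params = params_from_json_list(x$params)),
            class = "joint_model")
}
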