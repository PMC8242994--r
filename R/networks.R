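# Trainable classifiers: the OPCNN (outer-product CNN) and the DMNN family
# (deep multimodal networks with early/intermediate/late fusion), plus
# unimodal reference networks. All share a common fit/predict contract.

#' OPCNN architecture configuration
#'
#' The OPCNN embeds each modality with an FC(`embed_dim`)+ReLU layer, forms
#' the augmented outer product of the two embeddings (a
#' `(embed_dim+1) x (embed_dim+1)` one-channel image), passes it through
#' `n_residual_blocks` residual blocks (each `convs_per_block` convolution
#' layers with `kernels` kernels of size `kernel_size`, stride 1, 'same'
#' padding, ReLU; identity skip, or a 1x1 projection where the channel
#' count changes; ReLU after the addition), flattens, and finishes with the
#' fully connected head. With the defaults the network has exactly 5 FC
#' layers (two embeddings + `head`) and 9 convolution layers.
#'
#' @param embed_dim Width of the two modality embeddings (default 50).
#' @param n_residual_blocks Number of residual blocks (default 3).
#' @param convs_per_block Convolutions per block (default 3).
#' @param kernels Number of kernels per convolution (default 32).
#' @param kernel_size Square kernel size (default 3).
#' @param stride Convolution stride; only 1 is supported.
#' @param head Fully connected head widths, ending in 1 (sigmoid output);
#'   default `c(100, 50, 1)`.
#' @param p1,p2 Expected input dimensions of the two modalities
#'   (defaults 13 and 34); [fit()] refuses data of other widths.
#' @param seed Seed for parameter initialisation.
#' @return A list of class `"opcnn_config"`.
#' @export
opcnn_config <- function(embed_dim = 50L, n_residual_blocks = 3L,
                         convs_per_block = 3L, kernels = 32L,
                         kernel_size = 3L, stride = 1L,
                         head = c(100L, 50L, 1L), p1 = 13L, p2 = 34L,
                         seed = 1L) {
  cfg <- list(embed_dim = as.integer(embed_dim),
              n_residual_blocks = as.integer(n_residual_blocks),
              convs_per_block = as.integer(convs_per_block),
              kernels = as.integer(kernels),
              kernel_size = as.integer(kernel_size),
              stride = as.integer(stride),
              head = as.integer(head),
              p1 = as.integer(p1), p2 = as.integer(p2),
              seed = as.integer(seed))
  if (any(c(cfg$embed_dim, cfg$n_residual_blocks, cfg$convs_per_block,
            cfg$kernels, cfg$kernel_size, cfg$head, cfg$p1, cfg$p2) < 1L)) {
    opcnn_stop("all architecture counts must be >= 1", "config_error")
  }
  if (cfg$stride != 1L) {
    opcnn_stop("only stride 1 is supported", "config_error")
  }
  if (cfg$head[length(cfg$head)] != 1L) {
    opcnn_stop("the last head width must be 1", "config_error")
  }
  structure(cfg, class = "opcnn_config")
}

#' Build an (untrained) OPCNN model
#'
#' Initialises all parameters (He-scaled normal draws under `cfg$seed`);
#' two builds with the same config produce identical parameters.
#'
#' @param cfg An [opcnn_config()].
#' @return An object of class `c("opcnn_model", "nn_model")`.
#' @export
build_opcnn <- function(cfg) {
  stopifnot(inherits(cfg, "opcnn_config"))
  S <- cfg$embed_dim + 1L
  geoms <- vector("list", cfg$n_residual_blocks)
  cin <- 1L
  for (i in seq_len(cfg$n_residual_blocks)) {
    geoms[[i]] <- resblock_geoms(S, S, cin, cfg$kernels,
                                 cfg$convs_per_block, cfg$kernel_size)
    cin <- cfg$kernels
  }
  flat_dim <- S * S * cfg$kernels
  params <- with_seed(cfg$seed, {
    head_in <- c(flat_dim, cfg$head[-length(cfg$head)])
    list(
      emb1 = dense_init(cfg$p1, cfg$embed_dim),
      emb2 = dense_init(cfg$p2, cfg$embed_dim),
      blocks = lapply(geoms, resblock_init),
      head = lapply(seq_along(cfg$head), function(i) {
        dense_init(head_in[i], cfg$head[i], final = i == length(cfg$head))
      })
    )
  })
  structure(list(kind = "opcnn", cfg = cfg, params = params, geoms = geoms,
                 p1 = cfg$p1, p2 = cfg$p2, trained = FALSE, history = NULL),
            class = c("opcnn_model", "nn_model"))
}

opcnn_forward <- function(model, X1, X2) {
  p <- model$params
  z1 <- dense_fwd(X1, p$emb1); f1 <- relu(z1)
  z2 <- dense_fwd(X2, p$emb2); f2 <- relu(z2)
  ao <- aug_outer_fwd(f1, f2)
  h <- ao$out
  bcaches <- vector("list", length(p$blocks))
  for (i in seq_along(p$blocks)) {
    bcaches[[i]] <- resblock_fwd(h, p$blocks[[i]], model$geoms[[i]])
    h <- bcaches[[i]]$out
  }
  hc <- dense_stack_fwd(h, p$head, final_linear = TRUE)
  list(logit = hc$out,
       cache = list(X1 = X1, X2 = X2, z1 = z1, z2 = z2, ao = ao,
                    bcaches = bcaches, hc = hc))
}

opcnn_backward <- function(model, cache, dlogit) {
  p <- model$params
  hb <- dense_stack_bwd(cache$hc, p$head, dlogit, final_linear = TRUE)
  d <- hb$dX
  gblocks <- vector("list", length(p$blocks))
  for (i in rev(seq_along(p$blocks))) {
    rb <- resblock_bwd(cache$bcaches[[i]], p$blocks[[i]], model$geoms[[i]], d)
    gblocks[[i]] <- rb$grads
    d <- rb$dX
  }
  ab <- aug_outer_bwd(cache$ao, d)
  d1 <- ab$dF1 * (cache$z1 > 0)
  d2 <- ab$dF2 * (cache$z2 > 0)
  g1 <- dense_bwd(cache$X1, p$emb1, d1)
  g2 <- dense_bwd(cache$X2, p$emb2, d2)
  list(emb1 = list(W = g1$dW, b = g1$db),
       emb2 = list(W = g2$dW, b = g2$db),
       blocks = gblocks, head = hb$grads)
}

#' DMNN architecture configuration
#'
#' Deep multimodal networks joining the two modalities at one of three
#' levels with one of five fusion operators:
#' \itemize{
#'   \item early: each modality through FC(50)+ReLU, fuse, then the
#'     FC(100)-FC(100)-FC(50)-FC(1) head;
#'   \item intermediate: each modality through FC(100)-FC(100)-FC(50)
#'     (FC(100)-FC(50) for the high-dimensional `tfl`/`mcf` operators),
#'     fuse, then an FC(100)-FC(50)-FC(1) head;
#'   \item late: each modality through its full FC(100)-FC(100)-FC(50)
#'     stack; the penultimate representations are concatenated into a final
#'     FC(1) (only concatenation is supported at the late level; averaging
#'     of the two branch probabilities is available via
#'     `late_join = "average_proba"`).
#' }
#' `tfl` and `mcf` are only available at the early and intermediate levels.
#' Hidden layers use ReLU; the output is a sigmoid.
#'
#' @param fusion_level `"early"`, `"intermediate"`, or `"late"`.
#' @param fusion_mode `"addition"`, `"product"`, `"concat"`, `"tfl"`,
#'   or `"mcf"`.
#' @param embed_dim Early-fusion embedding width (default 50).
#' @param branch_widths,head_widths Optional overrides of the per-modality
#'   and post-fusion stack widths.
#' @param mcf_d,mcf_k,mcf_variant MCF projection dimensions and interaction
#'   variant (see [mcf_interact()]); defaults d = k = 50, `"matmul"`.
#' @param late_join `"concat_penultimate"` (default) or `"average_proba"`.
#' @param p1,p2 Expected modality input dimensions.
#' @param seed Seed for parameter initialisation.
#' @return A list of class `"dmnn_config"`.
#' @export
dmnn_config <- function(fusion_level = c("early", "intermediate", "late"),
                        fusion_mode = c("concat", "addition", "product",
                                        "tfl", "mcf"),
                        embed_dim = 50L, branch_widths = NULL,
                        head_widths = NULL, mcf_d = 50L, mcf_k = 50L,
                        mcf_variant = c("matmul", "avg_elementwise"),
                        late_join = c("concat_penultimate", "average_proba"),
                        p1 = 13L, p2 = 34L, seed = 1L) {
  fusion_level <- match.arg(fusion_level)
  fusion_mode <- match.arg(fusion_mode)
  mcf_variant <- match.arg(mcf_variant)
  late_join <- match.arg(late_join)
  if (fusion_level == "late" && fusion_mode != "concat") {
    opcnn_stop("late fusion supports only concatenation", "config_error")
  }
  if (fusion_mode %in% c("tfl", "mcf") && fusion_level == "late") {
    opcnn_stop("tfl/mcf are available at the early and intermediate levels",
               "config_error")
  }
  branch_widths <- as.integer(branch_widths %||% switch(fusion_level,
    early = embed_dim,
    intermediate = if (fusion_mode %in% c("tfl", "mcf")) c(100L, 50L)
                   else c(100L, 100L, 50L),
    late = c(100L, 100L, 50L)))
  head_widths <- as.integer(head_widths %||% switch(fusion_level,
    early = c(100L, 100L, 50L, 1L),
    intermediate = c(100L, 50L, 1L),
    late = 1L))
  if (head_widths[length(head_widths)] != 1L) {
    opcnn_stop("the last head width must be 1", "config_error")
  }
  structure(list(fusion_level = fusion_level, fusion_mode = fusion_mode,
                 embed_dim = as.integer(embed_dim),
                 branch_widths = branch_widths, head_widths = head_widths,
                 mcf_d = as.integer(mcf_d), mcf_k = as.integer(mcf_k),
                 mcf_variant = mcf_variant, late_join = late_join,
                 p1 = as.integer(p1), p2 = as.integer(p2),
                 seed = as.integer(seed)),
            class = "dmnn_config")
}

#' Build an (untrained) DMNN model
#'
#' @param cfg A [dmnn_config()].
#' @return An object of class `c("dmnn_model", "nn_model")`.
#' @export
build_dmnn <- function(cfg) {
  stopifnot(inherits(cfg, "dmnn_config"))
  bw <- cfg$branch_widths
  rep_dim <- bw[length(bw)]
  fused_dim <- switch(cfg$fusion_mode,
    addition = rep_dim, product = rep_dim, concat = 2L * rep_dim,
    tfl = (rep_dim + 1L)^2, mcf = cfg$mcf_k)
  if (cfg$fusion_level == "late") fused_dim <- 2L * rep_dim
  params <- with_seed(cfg$seed, {
    mk_branch <- function(p_in) {
      ins <- c(p_in, bw[-length(bw)])
      lapply(seq_along(bw), function(i) dense_init(ins[i], bw[i]))
    }
    out <- list(branch1 = mk_branch(cfg$p1), branch2 = mk_branch(cfg$p2))
    if (cfg$fusion_mode == "mcf" && cfg$fusion_level != "late") {
      d <- min(cfg$mcf_d, rep_dim)
      out$mcf <- list(
        W1 = matrix(stats::rnorm(d * rep_dim, sd = sqrt(1 / rep_dim)),
                    d, rep_dim),
        W2 = matrix(stats::rnorm(d * rep_dim, sd = sqrt(1 / rep_dim)),
                    d, rep_dim),
        W3 = matrix(stats::rnorm(cfg$mcf_k * d, sd = sqrt(1 / d)),
                    cfg$mcf_k, d))
    }
    if (cfg$fusion_level == "late" && cfg$late_join == "average_proba") {
      out$out1 <- dense_init(rep_dim, 1L, final = TRUE)
      out$out2 <- dense_init(rep_dim, 1L, final = TRUE)
    } else {
      hw <- cfg$head_widths
      ins <- c(fused_dim, hw[-length(hw)])
      out$head <- lapply(seq_along(hw), function(i) {
        dense_init(ins[i], hw[i], final = i == length(hw))
      })
    }
    out
  })
  # row-major reordering so the in-network TFL matches tfl_fuse() exactly
  tfl_perm <- NULL
  if (cfg$fusion_mode == "tfl") {
    S <- rep_dim + 1L
    tfl_perm <- as.vector(t(matrix(seq_len(S * S), S, S)))
  }
  structure(list(kind = "dmnn", cfg = cfg, params = params,
                 tfl_perm = tfl_perm, p1 = cfg$p1, p2 = cfg$p2,
                 trained = FALSE, history = NULL),
            class = c("dmnn_model", "nn_model"))
}

dmnn_forward <- function(model, X1, X2) {
  p <- model$params
  cfg <- model$cfg
  b1 <- dense_stack_fwd(X1, p$branch1)
  b2 <- dense_stack_fwd(X2, p$branch2)
  cache <- list(b1 = b1, b2 = b2, X1 = X1, X2 = X2)
  if (cfg$fusion_level == "late" && cfg$late_join == "average_proba") {
    l1 <- dense_fwd(b1$out, p$out1)
    l2 <- dense_fwd(b2$out, p$out2)
    pr <- (stats::plogis(l1) + stats::plogis(l2)) / 2
    pr <- pmin(pmax(pr, 1e-12), 1 - 1e-12)
    cache$l1 <- l1; cache$l2 <- l2
    return(list(logit = stats::qlogis(pr), cache = cache))
  }
  mode <- if (cfg$fusion_level == "late") "concat" else cfg$fusion_mode
  z <- switch(mode,
    addition = b1$out + b2$out,
    product = b1$out * b2$out,
    concat = cbind(b1$out, b2$out),
    tfl = {
      ao <- aug_outer_fwd(b1$out, b2$out)
      cache$ao <- ao
      ao$out[, model$tfl_perm, drop = FALSE]
    },
    mcf = {
      mc <- mcf_batch_fwd(b1$out, b2$out, p$mcf, cfg$mcf_variant)
      cache$mc <- mc
      mc$out
    })
  hc <- dense_stack_fwd(z, p$head, final_linear = TRUE)
  cache$hc <- hc
  list(logit = hc$out, cache = cache)
}

dmnn_backward <- function(model, cache, dlogit) {
  p <- model$params
  cfg <- model$cfg
  grads <- list()
  if (cfg$fusion_level == "late" && cfg$late_join == "average_proba") {
    # dlogit is w.r.t. qlogis(pr); chain through pr = (s1 + s2)/2
    pr <- (stats::plogis(cache$l1) + stats::plogis(cache$l2)) / 2
    pr <- pmin(pmax(pr, 1e-12), 1 - 1e-12)
    dpr <- dlogit / (pr * (1 - pr))
    dl1 <- dpr * stats::plogis(cache$l1) * (1 - stats::plogis(cache$l1)) / 2
    dl2 <- dpr * stats::plogis(cache$l2) * (1 - stats::plogis(cache$l2)) / 2
    g1 <- dense_bwd(cache$b1$out, p$out1, dl1)
    g2 <- dense_bwd(cache$b2$out, p$out2, dl2)
    grads$out1 <- list(W = g1$dW, b = g1$db)
    grads$out2 <- list(W = g2$dW, b = g2$db)
    bb1 <- dense_stack_bwd(cache$b1, p$branch1, g1$dX)
    bb2 <- dense_stack_bwd(cache$b2, p$branch2, g2$dX)
    grads$branch1 <- bb1$grads
    grads$branch2 <- bb2$grads
    return(grads)
  }
  hb <- dense_stack_bwd(cache$hc, p$head, dlogit, final_linear = TRUE)
  grads$head <- hb$grads
  dz <- hb$dX
  mode <- if (cfg$fusion_level == "late") "concat" else cfg$fusion_mode
  r1 <- cache$b1$out
  r2 <- cache$b2$out
  d12 <- switch(mode,
    addition = list(d1 = dz, d2 = dz),
    product = list(d1 = dz * r2, d2 = dz * r1),
    concat = {
      w <- ncol(r1)
      list(d1 = dz[, seq_len(w), drop = FALSE],
           d2 = dz[, -seq_len(w), drop = FALSE])
    },
    tfl = {
      dao <- dz[, order(model$tfl_perm), drop = FALSE]
      ab <- aug_outer_bwd(cache$ao, dao)
      list(d1 = ab$dF1, d2 = ab$dF2)
    },
    mcf = {
      mb <- mcf_batch_bwd(cache$mc, p$mcf, cfg$mcf_variant, r1, r2, dz)
      grads$mcf <- mb$grads
      list(d1 = mb$dF1, d2 = mb$dF2)
    })
  bb1 <- dense_stack_bwd(cache$b1, p$branch1, d12$d1)
  bb2 <- dense_stack_bwd(cache$b2, p$branch2, d12$d2)
  grads$branch1 <- bb1$grads
  grads$branch2 <- bb2$grads
  grads
}

#' Unimodal reference network configuration
#'
#' A plain fully connected network on one modality only
#' (FC(100)-FC(100)-FC(50)-FC(1) by default), used as the unimodal baseline
#' that fusion models must beat on interaction-driven data.
#'
#' @param modality `"chemical"` (x1) or `"target"` (x2).
#' @param widths Hidden widths (default `c(100, 100, 50)`).
#' @param p1,p2 Modality input dimensions.
#' @param seed Seed for parameter initialisation.
#' @return A list of class `"unimodal_config"`.
#' @export
unimodal_config <- function(modality = c("chemical", "target"),
                            widths = c(100L, 100L, 50L),
                            p1 = 13L, p2 = 34L, seed = 1L) {
  modality <- match.arg(modality)
  structure(list(modality = modality, widths = as.integer(widths),
                 p1 = as.integer(p1), p2 = as.integer(p2),
                 seed = as.integer(seed)),
            class = "unimodal_config")
}

#' Build an (untrained) unimodal network
#'
#' @param cfg A [unimodal_config()].
#' @return An object of class `c("unimodal_model", "nn_model")`.
#' @export
build_unimodal <- function(cfg) {
  stopifnot(inherits(cfg, "unimodal_config"))
  p_in <- if (cfg$modality == "chemical") cfg$p1 else cfg$p2
  params <- with_seed(cfg$seed, {
    ins <- c(p_in, cfg$widths)
    stack <- lapply(seq_along(cfg$widths), function(i) {
      dense_init(ins[i], cfg$widths[i])
    })
    list(stack = stack,
         out = dense_init(cfg$widths[length(cfg$widths)], 1L, final = TRUE))
  })
  structure(list(kind = "unimodal", cfg = cfg, params = params,
                 p1 = cfg$p1, p2 = cfg$p2, trained = FALSE, history = NULL),
            class = c("unimodal_model", "nn_model"))
}

unimodal_forward <- function(model, X1, X2) {
  X <- if (model$cfg$modality == "chemical") X1 else X2
  sc <- dense_stack_fwd(X, model$params$stack)
  logit <- dense_fwd(sc$out, model$params$out)
  list(logit = logit, cache = list(sc = sc, X = X))
}

unimodal_backward <- function(model, cache, dlogit) {
  g <- dense_bwd(cache$sc$out, model$params$out, dlogit)
  bb <- dense_stack_bwd(cache$sc, model$params$stack, g$dX)
  list(stack = bb$grads, out = list(W = g$dW, b = g$db))
}

nn_forward <- function(model, X1, X2) {
  switch(model$kind,
         opcnn = opcnn_forward(model, X1, X2),
         dmnn = dmnn_forward(model, X1, X2),
         unimodal = unimodal_forward(model, X1, X2),
         opcnn_stop(sprintf("unknown model kind '%s'", model$kind),
                    "config_error"))
}

nn_backward <- function(model, cache, dlogit) {
  switch(model$kind,
         opcnn = opcnn_backward(model, cache, dlogit),
         dmnn = dmnn_backward(model, cache, dlogit),
         unimodal = unimodal_backward(model, cache, dlogit))
}

#' Training configuration
#'
#' Adam optimisation of the (optionally class-weighted) binary
#' cross-entropy. With `loss = "bce"` the class weights are forced to
#' (1, 1); `loss = "weighted_bce"` weights each term by `w_pos` or `w_neg`.
#' Training stops early when the epoch training loss has not improved for
#' `patience` epochs.
#'
#' @param loss `"bce"` or `"weighted_bce"`.
#' @param class_weights `c(w_pos, w_neg)`; see [class_weights()].
#' @param learning_rate Adam step size (> 0; default 1e-3).
#' @param epochs Maximum epochs (>= 1).
#' @param batch_size Minibatch size.
#' @param patience Early-stopping patience in epochs.
#' @param seed Seed controlling shuffling.
#' @return A list of class `"train_config"`.
#' @export
train_config <- function(loss = c("bce", "weighted_bce"),
                         class_weights = c(1, 1), learning_rate = 1e-3,
                         epochs = 200L, batch_size = 32L, patience = 20L,
                         seed = 1L) {
  loss <- match.arg(loss)
  if (learning_rate <= 0) opcnn_stop("learning_rate must be > 0",
                                     "config_error")
  if (epochs < 1L) opcnn_stop("epochs must be >= 1", "config_error")
  if (loss == "bce") class_weights <- c(1, 1)
  structure(list(loss = loss,
                 class_weights = as.numeric(class_weights),
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 patience = as.integer(patience), seed = as.integer(seed)),
            class = "train_config")
}

#' Fit a neural network model
#'
#' Minimises the mean (class-weighted) binary cross-entropy with Adam over
#' shuffled minibatches. Imputation and scaling are the caller's
#' responsibility (see [cross_validate()], which fits both on the training
#' fold only). Deterministic given the model/config seeds and a fixed BLAS
#' thread policy.
#'
#' @param object A built model ([build_opcnn()], [build_dmnn()],
#'   [build_unimodal()]).
#' @param data A fully imputed [bimodal_dataset()] containing both classes,
#'   or a list with elements `x1`, `x2`, `y`.
#' @param tcfg A [train_config()].
#' @param ... Unused.
#' @return The trained model; `$history` holds the per-epoch mean training
#'   loss.
#' @export
fit <- function(object, ...) UseMethod("fit")

#' @rdname fit
#' @export
fit.nn_model <- function(object, data, tcfg = train_config(), ...) {
  d <- as_xy(data)
  if (ncol(d$x1) != object$p1 || ncol(d$x2) != object$p2) {
    opcnn_stop(sprintf(
      "model expects modality widths (%d, %d), data has (%d, %d)",
      object$p1, object$p2, ncol(d$x1), ncol(d$x2)), "dimension_error")
  }
  y <- d$y
  if (length(unique(y)) < 2L) {
    opcnn_stop("training data must contain both classes", "data_error")
  }
  w <- ifelse(y == 1, tcfg$class_weights[1], tcfg$class_weights[2])
  n <- length(y)
  params <- object$params
  state <- adam_init(params)
  history <- numeric(0)
  best <- Inf
  stall <- 0L
  with_seed(tcfg$seed, {
    for (epoch in seq_len(tcfg$epochs)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = tcfg$batch_size)
      ep_loss <- 0
      for (s in starts) {
        bi <- ord[s:min(s + tcfg$batch_size - 1L, n)]
        mdl <- object
        mdl$params <- params
        fw <- nn_forward(mdl, d$x1[bi, , drop = FALSE],
                         d$x2[bi, , drop = FALSE])
        lo <- wbce_loss(as.numeric(fw$logit), y[bi], w[bi])
        if (!is.finite(lo$loss)) {
          opcnn_stop(sprintf(
            "NaN/Inf training loss at epoch %d (learning rate %g)",
            epoch, tcfg$learning_rate), "training_error")
        }
        grads <- nn_backward(mdl, fw$cache,
                             matrix(lo$dlogit, length(bi), 1L))
        upd <- adam_step(params, grads, state, tcfg$learning_rate)
        params <- upd$params
        state <- upd$state
        ep_loss <- ep_loss + lo$loss * length(bi)
      }
      ep_loss <- ep_loss / n
      history <- c(history, ep_loss)
      if (ep_loss < best - 1e-6) {
        best <- ep_loss
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= tcfg$patience) break
      }
    }
  })
  object$params <- params
  object$trained <- TRUE
  object$history <- history
  object
}

as_xy <- function(data) {
  if (inherits(data, "bimodal_dataset")) {
    split_modalities(data)
  } else if (is.list(data) && all(c("x1", "x2", "y") %in% names(data))) {
    list(x1 = as.matrix(data$x1), x2 = as.matrix(data$x2),
         y = check_binary(data$y, "y"))
  } else {
    opcnn_stop("data must be a bimodal_dataset or a list(x1, x2, y)",
               "data_error")
  }
}

#' Predict class probabilities
#'
#' One sigmoid score in (0, 1) per row, in row order.
#'
#' @param model A trained model.
#' @param data A [bimodal_dataset()] or list with `x1`, `x2`.
#' @param ... Unused.
#' @return Numeric vector of probabilities.
#' @export
predict_proba <- function(model, data, ...) UseMethod("predict_proba")

#' @rdname predict_proba
#' @export
predict_proba.nn_model <- function(model, data, ...) {
  x1 <- if (inherits(data, "bimodal_dataset")) data$x1 else as.matrix(data$x1)
  x2 <- if (inherits(data, "bimodal_dataset")) data$x2 else as.matrix(data$x2)
  if (anyNA(x1) || anyNA(x2)) {
    opcnn_stop("prediction data contains missing values; impute first",
               "data_error")
  }
  if (ncol(x1) != model$p1 || ncol(x2) != model$p2) {
    opcnn_stop("prediction data has wrong modality widths", "dimension_error")
  }
  n <- nrow(x1)
  out <- numeric(n)
  for (s in seq(1L, n, by = 1024L)) {
    bi <- s:min(s + 1023L, n)
    fw <- nn_forward(model, x1[bi, , drop = FALSE], x2[bi, , drop = FALSE])
    out[bi] <- stats::plogis(as.numeric(fw$logit))
  }
  out
}

#' Structural audit of a network
#'
#' Counts fully connected layers, convolution layers, skip projections, and
#' trainable parameters. With the default configuration the OPCNN audit
#' reports exactly 5 FC layers and 9 convolution layers.
#'
#' @param model A built model.
#' @return A list with `n_fc`, `n_conv`, `n_proj`, `n_params`.
#' @export
model_audit <- function(model) {
  stopifnot(inherits(model, "nn_model"))
  p <- model$params
  count_params <- function(x) {
    if (is.null(x)) return(0)
    if (is.list(x)) return(sum(vapply(x, count_params, numeric(1))))
    length(x)
  }
  n_fc <- 0L
  n_conv <- 0L
  n_proj <- 0L
  if (model$kind == "opcnn") {
    n_fc <- 2L + length(p$head)
    for (b in p$blocks) {
      n_conv <- n_conv + length(b$convs)
      if (!is.null(b$proj)) n_proj <- n_proj + 1L
    }
  } else if (model$kind == "dmnn") {
    n_fc <- length(p$branch1) + length(p$branch2) +
      length(p$head %||% list()) +
      sum(!is.null(p$out1), !is.null(p$out2))
  } else {
    n_fc <- length(p$stack) + 1L
  }
  list(n_fc = n_fc, n_conv = n_conv, n_proj = n_proj,
       n_params = count_params(p))
}

#' @export
print.nn_model <- function(x, ...) {
  a <- model_audit(x)
  cat(sprintf("<%s model> inputs (%d, %d), %s\n", x$kind, x$p1, x$p2,
              if (x$trained) sprintf("trained (%d epochs)",
                                     length(x$history)) else "untrained"))
  cat(sprintf("  layers: %d fully connected, %d convolutional", a$n_fc,
              a$n_conv))
  if (a$n_proj > 0) cat(sprintf(" (+%d skip projection)", a$n_proj))
  cat(sprintf("\n  trainable parameters: %s\n",
              format(a$n_params, big.mark = ",")))
  invisible(x)
}

#' Save or restore a model checkpoint
#'
#' A checkpoint is a single RDS file holding the architecture config and
#' parameter blob; [load_model()] restores a model that predicts
#' identically.
#'
#' @param model A built or trained model.
#' @param path Checkpoint file path.
#' @return `save_model` returns `path` invisibly; `load_model` the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "nn_model") || inherits(model, "baseline_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "nn_model") && !inherits(model, "baseline_model")) {
    opcnn_stop("file does not contain an opcnn model checkpoint",
               "data_error")
  }
  model
}
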