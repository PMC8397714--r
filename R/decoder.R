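# Conditional sequence decoder d(.): maps a fingerprint vector to SMILES
# strings.  A stacked-LSTM language model over overlapping three-character
# substrings is conditioned on the fingerprint at every timestep (through a
# learned low-rank projection concatenated to the token one-hot).  Because
# consecutive substrings overlap by two characters, sampling is masked to
# overlap-consistent tokens and each sampled token contributes only its
# final character.  A nearest-neighbour decoder over a reference library
# serves as the desk-scale fallback and evaluation baseline.

PAD_CHAR <- "~"
TOK_BEGIN <- "<BEGIN>"
TOK_END <- "<END>"
TOK_PAD <- "<PAD>"

#' Tokenize a SMILES string into overlapping three-character substrings
#'
#' Single-step moving window of width three; strings shorter than three
#' characters become one token right-padded with `~`.
#'
#' @param smiles A non-empty SMILES string.
#' @return Character vector of tokens (without BEGIN/END markers).
#' @examples
#' tokenize_smiles("c1ccccc1")  # "c1c" "1cc" "ccc" "ccc" "ccc" "cc1"
#' @export
tokenize_smiles <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1 || !nzchar(smiles)) {
    stopf("tokenize_smiles: empty input")
  }
  n <- nchar(smiles)
  if (n < 3) {
    return(gsub(" ", PAD_CHAR, sprintf("%-3s", smiles), fixed = TRUE))
  }
  vapply(seq_len(n - 2), function(i) substr(smiles, i, i + 2), "")
}

#' Reconstruct a SMILES string from its token sequence
#' @param tokens Character vector as produced by [tokenize_smiles()].
#' @return The original string.
#' @export
detokenize <- function(tokens) {
  tokens <- tokens[!(tokens %in% c(TOK_BEGIN, TOK_END, TOK_PAD))]
  if (length(tokens) == 0) return("")
  out <- tokens[1]
  if (length(tokens) > 1) {
    out <- paste0(out, paste(substr(tokens[-1], 3, 3), collapse = ""))
  }
  gsub(PAD_CHAR, "", out, fixed = TRUE)
}

# Vocabulary over a training corpus: chemical tokens plus BEGIN/END/PAD.
build_vocab <- function(smiles_list) {
  toks <- sort(unique(unlist(lapply(smiles_list, tokenize_smiles))))
  tokens <- c(TOK_PAD, TOK_BEGIN, TOK_END, toks)
  index <- setNames(seq_along(tokens), tokens)
  # successor table for overlap-consistent sampling: for every token, the
  # ids of tokens whose first two characters equal its last two
  suffix <- substr(toks, 2, 3)
  prefix <- substr(toks, 1, 2)
  succ <- lapply(seq_along(toks), function(i) {
    if (grepl(PAD_CHAR, toks[i], fixed = TRUE)) return(integer(0))
    which(prefix == suffix[i]) + 3L
  })
  list(tokens = tokens, index = index, n = length(tokens),
       succ = succ, chem_ids = seq_along(toks) + 3L)
}

encode_tokens <- function(vocab, smiles) {
  toks <- tokenize_smiles(smiles)
  ids <- vocab$index[toks]
  if (any(is.na(ids))) return(NULL)  # not representable
  as.integer(c(vocab$index[[TOK_BEGIN]], ids, vocab$index[[TOK_END]]))
}

# ---- LSTM core -------------------------------------------------------------

lstm_init <- function(input_dim, hidden, n_layers, vocab_n, cond_dim) {
  layers <- lapply(seq_len(n_layers), function(l) {
    ind <- if (l == 1) input_dim else hidden
    b <- numeric(4 * hidden)
    b[hidden + 1:hidden] <- 1   # forget-gate bias: remember by default
    list(W = matrix(rnorm((ind + hidden) * 4 * hidden,
                          sd = 1 / sqrt(ind + hidden)),
                    ind + hidden, 4 * hidden),
         b = b)
  })
  list(proj = list(W = matrix(rnorm(5000 * cond_dim, sd = 1 / sqrt(5000)),
                              5000, cond_dim),
                   b = numeric(cond_dim)),
       layers = layers,
       out = list(W = matrix(rnorm(hidden * vocab_n, sd = 1 / sqrt(hidden)),
                             hidden, vocab_n),
                  b = numeric(vocab_n)))
}

lstm_cell_forward <- function(Wb, x, h, c) {
  H <- ncol(Wb$W) / 4
  z <- sweep(cbind(x, h) %*% Wb$W, 2, Wb$b, "+")
  i <- sigmoid(z[, 1:H, drop = FALSE])
  f <- sigmoid(z[, H + 1:H, drop = FALSE])
  g <- tanh(z[, 2 * H + 1:H, drop = FALSE])
  o <- sigmoid(z[, 3 * H + 1:H, drop = FALSE])
  c_new <- f * c + i * g
  h_new <- o * tanh(c_new)
  list(h = h_new, c = c_new, i = i, f = f, g = g, o = o, x = x, h_prev = h,
       c_prev = c, tc = tanh(c_new))
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# Forward + BPTT over a padded batch.  ids: batch x (T+1) matrix of token
# ids (BEGIN ... END, PAD-padded).  Returns loss and gradients.
lstm_batch_grad <- function(params, ids, cond, vocab_n, dropout = 0) {
  B <- nrow(ids); Tn <- ncol(ids) - 1
  H <- ncol(params$layers[[1]]$W) / 4
  L <- length(params$layers)
  condZ <- sweep(cond %*% params$proj$W, 2, params$proj$b, "+")
  condA <- tanh(condZ)

  h <- lapply(seq_len(L), function(l) matrix(0, B, H))
  c <- lapply(seq_len(L), function(l) matrix(0, B, H))
  caches <- vector("list", Tn)
  masks <- vector("list", Tn)
  probs <- vector("list", Tn)
  loss <- 0; n_tok <- 0

  for (t in seq_len(Tn)) {
    x_ids <- ids[, t]
    X <- matrix(0, B, vocab_n)
    X[cbind(seq_len(B), x_ids)] <- 1
    inp <- cbind(X, condA)
    step <- vector("list", L)
    for (l in seq_len(L)) {
      cf <- lstm_cell_forward(params$layers[[l]], inp, h[[l]], c[[l]])
      h[[l]] <- cf$h; c[[l]] <- cf$c
      out_h <- cf$h
      if (dropout > 0) {
        m <- matrix(rbinom(B * H, 1, 1 - dropout), B, H) / (1 - dropout)
        out_h <- out_h * m
        cf$drop <- m
      }
      step[[l]] <- cf
      inp <- out_h
    }
    caches[[t]] <- step
    logits <- sweep(inp %*% params$out$W, 2, params$out$b, "+")
    P <- softmax_rows(logits)
    probs[[t]] <- P
    y <- ids[, t + 1]
    valid <- y != 1L   # PAD id
    masks[[t]] <- valid
    pi <- P[cbind(seq_len(B), y)]
    loss <- loss + sum(-log(pmax(pi[valid], 1e-12)))
    n_tok <- n_tok + sum(valid)
  }
  loss <- loss / n_tok

  # gradients
  zerog <- function(p) lapply(p, function(x) x * 0)
  g_proj <- zerog(params$proj)
  g_out <- zerog(params$out)
  g_layers <- lapply(params$layers, zerog)
  dh_next <- lapply(seq_len(L), function(l) matrix(0, B, H))
  dc_next <- lapply(seq_len(L), function(l) matrix(0, B, H))
  d_condA <- matrix(0, B, ncol(condA))

  for (t in rev(seq_len(Tn))) {
    step <- caches[[t]]
    y <- ids[, t + 1]
    valid <- masks[[t]]
    dlogits <- probs[[t]]
    dlogits[cbind(seq_len(B), y)] <- dlogits[cbind(seq_len(B), y)] - 1
    dlogits[!valid, ] <- 0
    dlogits <- dlogits / n_tok
    top_h <- step[[L]]$h
    if (!is.null(step[[L]]$drop)) top_h <- top_h * step[[L]]$drop
    g_out$W <- g_out$W + crossprod(top_h, dlogits)
    g_out$b <- g_out$b + colSums(dlogits)
    d_inp <- dlogits %*% t(params$out$W)   # grad wrt layer-L dropped output
    for (l in rev(seq_len(L))) {
      cf <- step[[l]]
      dh <- d_inp
      if (!is.null(cf$drop)) dh <- dh * cf$drop
      dh <- dh + dh_next[[l]]
      dc <- dc_next[[l]] + dh * cf$o * (1 - cf$tc^2)
      do <- dh * cf$tc * cf$o * (1 - cf$o)
      di <- dc * cf$g * cf$i * (1 - cf$i)
      df <- dc * cf$c_prev * cf$f * (1 - cf$f)
      dg <- dc * cf$i * (1 - cf$g^2)
      dz <- cbind(di, df, dg, do)
      xin <- cbind(cf$x, cf$h_prev)
      g_layers[[l]]$W <- g_layers[[l]]$W + crossprod(xin, dz)
      g_layers[[l]]$b <- g_layers[[l]]$b + colSums(dz)
      dxin <- dz %*% t(params$layers[[l]]$W)
      nx <- ncol(cf$x)
      dx <- dxin[, 1:nx, drop = FALSE]
      dh_next[[l]] <- dxin[, nx + seq_len(H), drop = FALSE]
      dc_next[[l]] <- dc * cf$f
      if (l > 1) {
        d_inp <- dx   # gradient wrt (dropped) output of layer below
      } else {
        d_condA <- d_condA + dx[, vocab_n + seq_len(ncol(condA)), drop = FALSE]
      }
    }
  }
  dZ <- d_condA * (1 - condA^2)
  g_proj$W <- crossprod(cond, dZ)
  g_proj$b <- colSums(dZ)
  list(loss = loss,
       grads = list(proj = g_proj, layers = g_layers, out = g_out))
}

# global-norm gradient clipping stabilizes backpropagation through time
clip_grads <- function(flat, max_norm = 5) {
  total <- sqrt(sum(vapply(flat, function(g) {
    sum(g$W^2) + sum(g$b^2)
  }, 1)))
  if (total <= max_norm) return(flat)
  s <- max_norm / total
  lapply(flat, function(g) list(W = g$W * s, b = g$b * s))
}

flatten_params <- function(p) c(list(p$proj), p$layers, list(p$out))
unflatten_params <- function(flat, L) {
  list(proj = flat[[1]], layers = flat[1 + seq_len(L)], out = flat[[L + 2]])
}

#' Train the conditional SMILES decoder
#'
#' Trains the stacked-LSTM substring language model on
#' `(fingerprint, molecule)` pairs by minimizing the per-token cross
#' entropy, teacher-forced on the canonical SMILES, conditioned on the
#' fingerprint at every step.
#'
#' @param pairs List of pairs: each element `list(fp, molecule)`.
#' @param hyper A [train_config()]; `hidden` gives the LSTM layer sizes
#'   (default desk scale `c(64, 64)`; the full-scale model is `rep(500, 3)`).
#' @param cond_dim Width of the learned fingerprint projection fed to each
#'   timestep.
#' @return A `decoder_model`.
#' @export
train_decoder <- function(pairs, hyper = train_config(epochs = 30),
                          cond_dim = 32) {
  if (length(pairs) == 0) stopf("train_decoder: empty dataset")
  mols <- lapply(pairs, function(p) as_molecule(p[[2]]))
  if (any(!vapply(mols, function(m) m$is_valid, TRUE))) {
    stopf("train_decoder: all molecules must be valid")
  }
  smiles <- vapply(mols, function(m) m$smiles_canonical, "")
  vocab <- build_vocab(smiles)
  seqs <- lapply(smiles, function(s) encode_tokens(vocab, s))
  fps <- do.call(rbind, lapply(pairs, function(p) as.numeric(p[[1]])))
  n <- length(seqs)
  hidden <- hyper$hidden[1]
  n_layers <- length(hyper$hidden)
  if (length(unique(hyper$hidden)) > 1) {
    stopf("train_decoder: LSTM layers must share one width")
  }
  input_dim <- vocab$n + cond_dim

  with_seed(hyper$seed, {
    params <- lstm_init(input_dim, hidden, n_layers, vocab$n, cond_dim)
    # fingerprint projection input dim must match the fingerprints given
    if (ncol(fps) != nrow(params$proj$W)) {
      params$proj$W <- matrix(rnorm(ncol(fps) * cond_dim,
                                    sd = 1 / sqrt(ncol(fps))),
                              ncol(fps), cond_dim)
    }
    flat <- flatten_params(params)
    st <- adam_new(flat)
    losses <- numeric(hyper$epochs)
    # length-sorted batches cut padding waste roughly in half; the batch
    # order is shuffled every epoch
    by_len <- order(vapply(seqs, length, 1L))
    starts <- seq(1, n, by = hyper$batch_size)
    for (ep in seq_len(hyper$epochs)) {
      ep_loss <- 0; nb <- 0
      for (start in sample(starts)) {
        b <- by_len[start:min(start + hyper$batch_size - 1, n)]
        lens <- vapply(seqs[b], length, 1L)
        Tmax <- max(lens)
        ids <- matrix(1L, length(b), Tmax)  # PAD id = 1
        for (r in seq_along(b)) ids[r, seq_len(lens[r])] <- seqs[[b[r]]]
        res <- lstm_batch_grad(params, ids, fps[b, , drop = FALSE],
                               vocab$n, hyper$dropout)
        ep_loss <- ep_loss + res$loss; nb <- nb + 1
        gflat <- clip_grads(flatten_params(res$grads))
        r2 <- adam_step(flat, gflat, st, hyper$lr)
        flat <- r2$params; st <- r2$state
        params <- unflatten_params(flat, n_layers)
      }
      losses[ep] <- ep_loss / nb
    }
    structure(list(params = params, vocab = vocab, hidden = hidden,
                   n_layers = n_layers, cond_dim = cond_dim,
                   losses = losses, hyper = hyper),
              class = "decoder_model")
  })
}

#' Decode fingerprints to SMILES strings
#'
#' Ancestral sampling from the conditional language model: at every step the
#' next-token distribution is conditioned on the current token and the
#' fingerprint, masked to tokens consistent in their two-character overlap
#' with the current one.  Samples that reach `max_len` without emitting the
#' end marker are returned truncated; no validity guarantee is made -- run
#' [inspect_validity()] on the results.
#'
#' @param model A `decoder_model`.
#' @param fp Fingerprint vector to condition on.
#' @param n_samples Number of strings to sample.
#' @param max_len Maximum SMILES length in characters.
#' @param seed RNG seed for reproducible sampling.
#' @return Character vector of up to `n_samples` SMILES strings.
#' @export
decode <- function(model, fp, n_samples = 10, max_len = 80, seed = NULL) {
  UseMethod("decode")
}

#' @export
decode.decoder_model <- function(model, fp, n_samples = 10, max_len = 80,
                                 seed = NULL) {
  if (n_samples < 1) stopf("decode: n_samples must be >= 1")
  vocab <- model$vocab
  V <- vocab$n
  H <- model$hidden
  L <- model$n_layers
  cond1 <- tanh(matrix(as.numeric(fp), 1) %*% model$params$proj$W +
                  matrix(model$params$proj$b, 1))
  max_tokens <- max(1L, max_len - 2L)
  with_seed(seed, {
    B <- n_samples
    cond <- cond1[rep(1, B), , drop = FALSE]
    h <- lapply(seq_len(L), function(l) matrix(0, B, H))
    c <- lapply(seq_len(L), function(l) matrix(0, B, H))
    prev <- rep(vocab$index[[TOK_BEGIN]], B)
    done <- rep(FALSE, B)
    out_tokens <- vector("list", B)
    for (step in seq_len(max_tokens)) {
      X <- matrix(0, B, V)
      X[cbind(seq_len(B), prev)] <- 1
      inp <- cbind(X, cond)
      for (l in seq_len(L)) {
        cf <- lstm_cell_forward(model$params$layers[[l]], inp, h[[l]], c[[l]])
        h[[l]] <- cf$h; c[[l]] <- cf$c
        inp <- cf$h
      }
      P <- softmax_rows(sweep(inp %*% model$params$out$W, 2,
                              model$params$out$b, "+"))
      nxt <- prev
      for (r in seq_len(B)) {
        if (done[r]) next
        allowed <- if (prev[r] == vocab$index[[TOK_BEGIN]]) {
          vocab$chem_ids
        } else {
          c(vocab$index[[TOK_END]], vocab$succ[[prev[r] - 3L]])
        }
        p <- P[r, allowed]
        if (sum(p) <= 0) {
          nxt[r] <- vocab$index[[TOK_END]]
        } else {
          nxt[r] <- allowed[sample.int(length(allowed), 1, prob = p)]
        }
        if (nxt[r] == vocab$index[[TOK_END]]) {
          done[r] <- TRUE
        } else {
          out_tokens[[r]] <- c(out_tokens[[r]], vocab$tokens[nxt[r]])
        }
      }
      prev <- nxt
      if (all(done)) break
    }
    vapply(out_tokens, function(tk) {
      if (is.null(tk)) "" else substr(detokenize(tk), 1, max_len)
    }, "")
  })
}

# ---- nearest-neighbour decoder --------------------------------------------

#' Nearest-neighbour fallback decoder
#'
#' Builds a decoder over a reference library of `(fingerprint, molecule)`
#' pairs; decoding a query fingerprint returns the library molecule with
#' maximal Tanimoto similarity (ties broken by canonical-SMILES
#' lexicographic order).
#'
#' @param pairs List of `list(fp, molecule)` pairs.
#' @param k_neighbors Neighbourhood size for stochastic decoding: samples
#'   are drawn from the `k_neighbors` most similar library molecules.
#' @param beta Sharpness of the similarity weighting within that
#'   neighbourhood (probability proportional to `tanimoto^beta`).
#'   `nn_decode()` itself is always the deterministic maximum.
#' @return An `nn_decoder` object (also accepted wherever a decoder is).
#' @export
nn_decoder <- function(pairs, k_neighbors = 16, beta = 2) {
  if (length(pairs) == 0) stopf("nn_decoder: empty library")
  M <- do.call(rbind, lapply(pairs, function(p) fp_binarize(as.numeric(p[[1]]))))
  smiles <- vapply(pairs, function(p) as_molecule(p[[2]])$smiles_canonical, "")
  structure(list(M = M, Mt = t(M), smiles = smiles, row_bits = rowSums(M),
                 k_neighbors = k_neighbors, beta = beta),
            class = "nn_decoder")
}

nn_similarities <- function(dec, fp) {
  q <- fp_binarize(as.numeric(fp))
  inter <- as.numeric(dec$M %*% q)
  uni <- dec$row_bits + sum(q) - inter
  ifelse(uni == 0, 1, inter / uni)
}

#' Nearest-neighbour decode
#'
#' @param library An [nn_decoder()] object or a list of pairs.
#' @param fp Query fingerprint.
#' @param k Number of nearest neighbours to return.
#' @return A [molecule] when `k = 1`, else a list of molecules ordered by
#'   decreasing similarity.
#' @export
nn_decode <- function(library, fp, k = 1) {
  dec <- if (inherits(library, "nn_decoder")) library else nn_decoder(library)
  sim <- nn_similarities(dec, fp)
  ord <- order(-sim, dec$smiles)
  picks <- ord[seq_len(min(k, length(ord)))]
  mols <- lapply(dec$smiles[picks], canonicalize)
  if (k == 1) mols[[1]] else mols
}

nn_sample <- function(model, sim, n_samples, seed) {
  ord <- order(-sim, model$smiles)
  nb <- ord[seq_len(min(model$k_neighbors, length(ord)))]
  w <- sim[nb]^model$beta
  if (sum(w) <= 0) w <- rep(1, length(nb))
  with_seed(seed, {
    idx <- nb[sample.int(length(nb), n_samples, replace = TRUE, prob = w)]
    model$smiles[idx]
  })
}

#' @export
decode.nn_decoder <- function(model, fp, n_samples = 10, max_len = 80,
                              seed = NULL) {
  # conditional stochastic decode: library molecules drawn from the query's
  # k-nearest neighbourhood with probability proportional to
  # tanimoto(fp, member)^beta -- the desk-scale analogue of sampling the
  # conditional sequence model (a single deterministic decode is available
  # via nn_decode)
  if (n_samples < 1) stopf("decode: n_samples must be >= 1")
  nn_sample(model, nn_similarities(model, fp), n_samples, seed)
}

# ---- evaluation metrics ----------------------------------------------------

#' Validity rate of decoded samples
#'
#' @param model A decoder (`decoder_model` or `nn_decoder`).
#' @param fps List of fingerprints to condition on.
#' @param n_samples Samples per fingerprint.
#' @param max_len Maximum SMILES length.
#' @param seed RNG seed.
#' @return Fraction of all decoded samples passing [inspect_validity()].
#' @export
validity_rate <- function(model, fps, n_samples = 10, max_len = 80,
                          seed = NULL) {
  if (length(fps) == 0) stopf("validity_rate: no fingerprints")
  all_valid <- 0; all_n <- 0
  for (i in seq_along(fps)) {
    ss <- decode(model, fps[[i]], n_samples, max_len,
                 seed = derive_seed(seed, paste0("vr", i)))
    all_n <- all_n + length(ss)
    all_valid <- all_valid + sum(vapply(ss, function(s) {
      inspect_validity(s)$valid
    }, TRUE))
  }
  all_valid / all_n
}

#' Reconstructability of a decoder on a test set
#'
#' Fraction of test molecules whose canonical SMILES appears among
#' `n_strings` samples conditioned on the molecule's own fingerprint.
#'
#' @param model A decoder.
#' @param test List of `list(fp, molecule)` pairs.
#' @param n_strings Samples per molecule (the full-scale protocol uses
#'   10000; scale down for desk use).
#' @param max_len Maximum SMILES length.
#' @param seed RNG seed.
#' @return Fraction in [0, 1].
#' @export
reconstructability <- function(model, test, n_strings = 10000, max_len = 80,
                               seed = NULL) {
  if (length(test) == 0) stopf("reconstructability: empty test set")
  hits <- vapply(seq_along(test), function(i) {
    target <- as_molecule(test[[i]][[2]])$smiles_canonical
    ss <- decode(model, test[[i]][[1]], n_strings, max_len,
                 seed = derive_seed(seed, paste0("rc", i)))
    target %in% ss
  }, TRUE)
  mean(hits)
}

#' Save / load a decoder or predictor checkpoint
#'
#' Single-archive checkpoint holding config, weights and vocabulary.
#'
#' @param model A `decoder_model` or `predictor_model`.
#' @param path Destination file.
#' @return `save_model` returns `path` invisibly; `load_model` the model.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)
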