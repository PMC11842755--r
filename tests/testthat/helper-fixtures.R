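# Shared fixtures, built once per test file. Small montages and cached
# simulated sessions keep the suite fast while exercising the real
# pipeline.

fixture_env <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = fixture_env)) {
    assign(key, force(expr), envir = fixture_env)
  }
  get(key, envir = fixture_env)
}

tiny_montage <- function() cached("m8", make_montage(8))
small_montage <- function() cached("m16", make_montage(16))

# One strong-effect (day 5) and one null epoch set on the tiny montage.
strong_epochs <- function() cached("ep_strong", {
  simulate_epoch_set(learner_profile(), day = 5, "offline", tiny_montage(),
                     n_per_class = 8, seed = 42)
})
null_profile <- function() {
  learner_profile(base_discriminability = 0, learning_rate = 0,
                  emg_leakage = 0)
}
null_epochs <- function() cached("ep_null", {
  simulate_epoch_set(null_profile(), day = 1, "offline", tiny_montage(),
                     n_per_class = 8, seed = 42)
})

# A hand-built feature matrix with a planted mean shift: 24 trials x 6
# windows, `n_feat` features of which the first `n_sig` carry the class.
toy_features <- function(n_trials = 24, n_win = 6, n_feat = 30, n_sig = 5,
                         effect = 1.5, seed = 1) {
  withr::with_seed(seed, {
    cls <- rep(c("fo", "gi"), length.out = n_trials)
    n <- n_trials * n_win
    x <- matrix(rnorm(n * n_feat), n, n_feat)
    shift <- ifelse(rep(cls, each = n_win) == "fo", effect, -effect)
    x[, seq_len(n_sig)] <- x[, seq_len(n_sig)] + shift
    colnames(x) <- paste0("ch", rep(seq_len(n_feat %/% 5), each = 5),
                          "_", rep(seq_len(5) * 2, n_feat %/% 5))
    idx <- data.frame(channel = rep(paste0("ch", seq_len(n_feat %/% 5)),
                                    each = 5),
                      freq = rep(seq_len(5) * 2, n_feat %/% 5),
                      group = "scalp", stringsAsFactors = FALSE)
    structure(list(x = x, index = idx,
                   meta = data.frame(trial = rep(seq_len(n_trials),
                                                 each = n_win),
                                     onset = rep(seq_len(n_win), n_trials),
                                     label = rep(cls, each = n_win),
                                     stringsAsFactors = FALSE)),
              class = "feature_matrix")
  })
}

# 3-channel chain adjacency (1-2-3) for toy cluster tests.
chain_adjacency <- function(labels = c("A", "B", "C")) {
  a <- matrix(FALSE, 3, 3, dimnames = list(labels, labels))
  a[1, 2] <- a[2, 1] <- a[2, 3] <- a[3, 2] <- TRUE
  a
}

# Independent brute-force 3-channel cluster test by full sign-flip
# enumeration (the oracle for the permutation engine).
brute_cluster_test <- function(x, adj, alpha = 0.05, stat = "size") {
  n <- nrow(x)
  tval <- function(v) mean(v) / (sd(v) / sqrt(length(v)))
  tmap <- apply(x, 2, tval)
  thr <- qt(1 - alpha / 2, n - 1)
  comp_stats <- function(tm) {
    out <- list()
    for (sgn in c(1, -1)) {
      mask <- if (sgn > 0) tm > thr else tm < -thr
      lab <- rep(0L, length(tm))
      cur <- 0L
      for (i in seq_along(tm)) {   # chain graph: consecutive runs
        if (mask[i]) {
          if (i > 1 && mask[i - 1] && adj[i - 1, i]) lab[i] <- cur
          else { cur <- cur + 1L; lab[i] <- cur }
        }
      }
      for (g in setdiff(unique(lab), 0L)) {
        ch <- which(lab == g)
        out[[length(out) + 1]] <- list(channels = ch, sign = sgn,
                                       stat = if (stat == "size") length(ch)
                                              else sum(abs(tm[ch])))
      }
    }
    out
  }
  obs <- comp_stats(tmap)
  grid <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  null_max <- apply(grid, 1, function(s) {
    tm <- apply(x * s, 2, tval)
    cs <- comp_stats(tm)
    if (length(cs) == 0) 0 else max(vapply(cs, `[[`, numeric(1), "stat"))
  })
  lapply(obs, function(cl) {
    cl$p <- mean(null_max >= cl$stat)
    cl
  })
}
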