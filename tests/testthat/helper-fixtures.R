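# Shared fixtures, built once per test run and memoized. All synthetic:
# generated by the package's own simulator under fixed seeds.

.fx <- new.env(parent = emptyenv())

fx_memo <- function(name, builder) {
  if (is.null(.fx[[name]])) .fx[[name]] <- builder()
  .fx[[name]]
}

# A small deterministic track: straight crawl, no noise.
fx_track <- function(seconds = 6, action = "crawl", noise = 0, seed = 1) {
  sim <- simulate_track(sim_script(action, seconds,
                                   params = action_params(noise_sd = noise),
                                   seed = seed))
  sim$track
}

# Balanced labelled window pool over the six simulated actions.
fx_pool <- function() {
  fx_memo("pool", function()
    simulate_labelled_windows(120, seed = 101))
}

# Pre-trained encoder over the pool (shared across learning tests).
fx_encoder <- function() {
  fx_memo("encoder", function() {
    pool <- fx_pool()
    pretrain(pool$windows, train_config(epochs = 80, lr = 1e-3, seed = 1))
  })
}

# Train/test split of the pool, fixed.
fx_split <- function() {
  fx_memo("split", function() {
    pool <- fx_pool()
    te <- withr::with_seed(5, sample(seq_along(pool$windows),
                                     round(0.25 * length(pool$windows))))
    list(train = setdiff(seq_along(pool$windows), te), test = te)
  })
}

expect_track_valid <- function(track) {
  expect_silent(validate_track(track))
}

# ---- acceptance-scale fixtures (larger; shared across acceptance checks) ----

# 600 windows per action class with per-larva phenotype variation.
acc_pool <- function() {
  fx_memo("acc_pool", function() simulate_labelled_windows(600, seed = 2024))
}

# Fixed stratified split: 100 windows per class held out for evaluation.
acc_split <- function() {
  fx_memo("acc_split", function() {
    pool <- acc_pool()
    te <- withr::with_seed(77, {
      unlist(lapply(unique(pool$classes), function(cl)
        sample(which(pool$classes == cl), 100)))
    })
    list(train = setdiff(seq_along(pool$windows), te), test = sort(te))
  })
}

# Encoder pre-trained for 200 epochs on 1800 of 2000 unlabelled windows,
# with the remaining 200 (10%) kept as a held-out reconstruction set.
acc_pretrain <- function() {
  fx_memo("acc_pretrain", function() {
    pool <- acc_pool()
    sp <- acc_split()
    pick <- withr::with_seed(88, sample(sp$train, 2000))
    held <- pick[1:200]
    used <- pick[201:2000]
    model <- pretrain(pool$windows[used],
                      train_config(epochs = 200, lr = 1e-3, seed = 1))
    list(model = model, used = used, held = held)
  })
}
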