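# Shared fixtures: tiny libraries, an independent recursive enumerator, and
# small planted-truth datasets. Everything is generated in code at test
# time under fixed seeds.

# Independent oracle for library enumeration: plain recursion, no reuse of
# the package's expand.grid path.
recursive_enumerate <- function(alphabets) {
  if (length(alphabets) == 0) return("")
  rest <- recursive_enumerate(alphabets[-1])
  unlist(lapply(sort(alphabets[[1]]), function(b) paste0(b, rest)))
}

tiny_positions <- c("H4", "H5", "H6", "H7")

# 256-variant library over four positions with a planted positive synergy;
# used by model/attribution/CRV recovery tests.
tiny_truth <- function(seed = 1, delta = 2, effect_sd = 2) {
  make_truth(positions = tiny_positions,
             effect_sd = effect_sd, intercept = -2,
             pairwise = data.frame(f1 = "H6_T", f2 = "H7_G", delta = delta),
             seed = seed)
}

# Train a small model on noiseless oracle efficiencies of a tiny truth.
# Small batches and a raised learning rate converge quickly at this scale.
fit_tiny_model <- function(truth, seed = 1, epochs = 150,
                           hidden = c(32, 16), batch_size = 16,
                           learning_rate = 3e-3, patience = 30) {
  oracle <- truth_oracle(truth)
  enc <- one_hot_encode(oracle$sequence, truth$positions)
  y <- oracle$efficiency
  n <- length(y)
  set.seed(seed)
  val <- sort(sample.int(n, round(n / 5)))
  tr <- setdiff(seq_len(n), val)
  model <- mlp_train(enc[tr, ], y[tr], enc[val, ], y[val],
                     mlp_config(hidden = hidden, max_epochs = epochs,
                                batch_size = batch_size,
                                learning_rate = learning_rate,
                                patience = patience,
                                dropout = 0, seed = seed))
  list(model = model, enc = enc, y = y, oracle = oracle,
       train_idx = tr, val_idx = val)
}

# CRV record for a synthetic half-line mode at a given angle (degrees) and
# approximate length; points are spread along the ray so the fitted record
# reproduces the angle.
a2rec <- function(angle_deg, length = 1) {
  r <- seq(length / 50, length, length.out = 50)
  a <- angle_deg * pi / 180
  fit_crv(cbind(cos(a) * r, sin(a) * r))
}

# A deterministic linear "model" for closed-form attribution checks.
linear_predictor <- function(weights, intercept = 0) {
  function(m) as.vector(as.matrix(m) %*% weights) + intercept
}
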