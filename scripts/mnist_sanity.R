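#!/usr/bin/env Rscript
# Opt-in MNIST sanity run (requires the four IDX files; not downloaded).
# A 784-64-10 network, T = 20, 10,000 training samples, 1 epoch; expected
# test accuracy above 90% in roughly ten minutes on one CPU.
# Usage: Rscript scripts/mnist_sanity.R --mnist-dir <dir> [--seed <int>]

library(gsdsnn)

args <- commandArgs(trailingOnly = TRUE)
opt <- list(seed = 1L, dir = NULL)
i <- 1
while (i < length(args) + 1) {
  if (args[i] == "--mnist-dir") { opt$dir <- args[i + 1]; i <- i + 2 }
  else if (args[i] == "--seed") { opt$seed <- as.integer(args[i + 1]); i <- i + 2 }
  else i <- i + 1
}
if (is.null(opt$dir)) stop("--mnist-dir is required (train/t10k IDX files)")

train <- read_idx(file.path(opt$dir, "train-images-idx3-ubyte"),
                  file.path(opt$dir, "train-labels-idx1-ubyte"))
test <- read_idx(file.path(opt$dir, "t10k-images-idx3-ubyte"),
                 file.path(opt$dir, "t10k-labels-idx1-ubyte"))
keep <- seq_len(10000)
train$images <- train$images[keep, ]; train$labels <- train$labels[keep]

params <- pinned_params(1e-3, t_max = 0.1)    # linear-response baseline
net <- network_config(c(784, 64, 10), T = 20)
arrays <- lapply(1:2, function(l)
  synapse_array(c(784, 64)[l], c(64, 10)[l], params,
                variation_config(rng_seed = opt$seed), seed_offset = l))
cfg <- train_config(T = 20, epochs = 1, seed = opt$seed)
tr <- train_snn(train, test, arrays, net, cfg, verbose = TRUE)
cat(sprintf("MNIST sanity accuracy (1 epoch, 10k samples): %.4f\n",
            tr$epoch_accuracy[1]))
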