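#!/usr/bin/env Rscript
# Opt-in full-scale MNIST reproduction (requires the four IDX files and
# hours of CPU). Trains the 784-256-10 network with T = 20 and batch size
# 1 on the full 60k training set; pass --hidden4 for the four-hidden-layer
# 784-256-256-256-256-10 network with batch size 100 and the
# learning-rate schedule (0.2x at epoch 11).
# Usage: Rscript scripts/mnist_full.R --mnist-dir <dir> [--epochs N]
#        [--hidden4] [--seed <int>]

library(gsdsnn)

args <- commandArgs(trailingOnly = TRUE)
opt <- list(seed = 1L, dir = NULL, epochs = 20L, hidden4 = FALSE)
i <- 1
while (i < length(args) + 1) {
  if (args[i] == "--mnist-dir") { opt$dir <- args[i + 1]; i <- i + 2 }
  else if (args[i] == "--epochs") { opt$epochs <- as.integer(args[i + 1]); i <- i + 2 }
  else if (args[i] == "--seed") { opt$seed <- as.integer(args[i + 1]); i <- i + 2 }
  else if (args[i] == "--hidden4") { opt$hidden4 <- TRUE; i <- i + 1 }
  else i <- i + 1
}
if (is.null(opt$dir)) stop("--mnist-dir is required (train/t10k IDX files)")

train <- read_idx(file.path(opt$dir, "train-images-idx3-ubyte"),
                  file.path(opt$dir, "train-labels-idx1-ubyte"))
test <- read_idx(file.path(opt$dir, "t10k-images-idx3-ubyte"),
                 file.path(opt$dir, "t10k-labels-idx1-ubyte"))

sizes <- if (opt$hidden4) c(784, 256, 256, 256, 256, 10) else c(784, 256, 10)
params <- pinned_params(1e-3, t_max = 0.1)    # linear-response baseline
net <- network_config(sizes, T = 20)
arrays <- lapply(seq_len(length(sizes) - 1), function(l)
  synapse_array(sizes[l], sizes[l + 1], params,
                variation_config(rng_seed = opt$seed), seed_offset = l))
cfg <- train_config(T = 20,
                    batch_size = if (opt$hidden4) 100 else 1,
                    epochs = opt$epochs,
                    lr_schedule = if (opt$hidden4) list(c(11, 0.2)) else list(),
                    seed = opt$seed)
tr <- train_snn(train, test, arrays, net, cfg, verbose = TRUE)
cat(sprintf("final MNIST accuracy: %.4f\n",
            utils::tail(tr$epoch_accuracy, 1)))
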