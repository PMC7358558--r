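# Differential-pair crossbar arrays: signed weights W = G+ - G-, forward
# and transposed analog reads, and the parallel bias-selective update phase.

#' Differential-pair synapse array
#'
#' A signed weight `W[i, j] = G+[i, j] - G-[i, j]` is realized by a pair of
#' unipolar devices. Both grids share shape, curve parameters and variation
#' config; device-to-device draws and stuck masks are sampled independently
#' per grid from the variation seed.
#'
#' @param n_pre,n_post array dimensions (pre- and post-synaptic neurons).
#' @param params a [device_params()] object.
#' @param variation a [variation_config()] object.
#' @param w_init either `NULL` (weights drawn uniformly in
#'   `[-w_scale, w_scale]` around mid-range conductances), or an
#'   `n_pre x n_post` matrix of initial weights (split symmetrically about
#'   mid-range).
#' @param w_scale half-width of the uniform weight initialization.
#' @param seed_offset mixed into the variation seed so several arrays in
#'   one network get independent device draws.
#' @return an object of class `synapse_array` with elements `g_plus`,
#'   `g_minus` (device grids), `params`, `variation`.
#' @export
synapse_array <- function(n_pre, n_post, params,
                          variation = variation_config(),
                          w_init = NULL, w_scale = 0.1, seed_offset = 0L) {
  stopifnot(n_pre >= 1, n_post >= 1)
  mid <- (params$g_min + params$g_max) / 2
  if (is.null(w_init)) {
    w_init <- with_seed(derive_seed(variation$rng_seed, seed_offset, 77L),
                        matrix(stats::runif(n_pre * n_post, -w_scale, w_scale),
                               n_pre, n_post))
  }
  stopifnot(all(dim(w_init) == c(n_pre, n_post)))
  gp <- sample_device_grid(c(n_pre, n_post), params, variation,
                           g_init = mid, seed_offset = 2L * seed_offset)
  gm <- sample_device_grid(c(n_pre, n_post), params, variation,
                           g_init = mid, seed_offset = 2L * seed_offset + 1L)
  gp$g[!gp$stuck] <- clamp(mid + w_init[!gp$stuck] / 2, params$g_min, params$g_max)
  gm$g[!gm$stuck] <- clamp(mid - w_init[!gm$stuck] / 2, params$g_min, params$g_max)
  structure(list(g_plus = gp, g_minus = gm,
                 params = params, variation = variation),
            class = "synapse_array")
}

#' Build a synapse array from explicit conductance matrices
#'
#' @param g_plus,g_minus conductance matrices of equal shape.
#' @inheritParams synapse_array
#' @return a `synapse_array`.
#' @export
synapse_array_from_g <- function(g_plus, g_minus, params,
                                 variation = variation_config()) {
  stopifnot(all(dim(g_plus) == dim(g_minus)))
  gp <- sample_device_grid(dim(g_plus), params, variation, seed_offset = 0L)
  gm <- sample_device_grid(dim(g_plus), params, variation, seed_offset = 1L)
  gp$g <- clamp(g_plus, params$g_min, params$g_max)
  gm$g <- clamp(g_minus, params$g_min, params$g_max)
  gp$g[gp$stuck] <- params$g_min
  gm$g[gm$stuck] <- params$g_min
  structure(list(g_plus = gp, g_minus = gm,
                 params = params, variation = variation),
            class = "synapse_array")
}

#' Effective signed weights of a synapse array
#' @param array a `synapse_array`.
#' @return the matrix `G+ - G-`.
#' @export
read_weights <- function(array) array$g_plus$g - array$g_minus$g

#' @export
print.synapse_array <- function(x, ...) {
  w <- read_weights(x)
  cat(sprintf("synapse_array %d x %d [%s mode], W in [%.3f, %.3f], %d stuck devices\n",
              nrow(w), ncol(w), x$params$mode, min(w), max(w),
              sum(x$g_plus$stuck) + sum(x$g_minus$stuck)))
  invisible(x)
}

#' Forward weighted-sum read of a spike vector
#'
#' Charge collected per output line when the binary spike vector drives the
#' array: `q_j = sum_i s_i (G+[i,j] - G-[i,j])`, i.e. the dense
#' matrix-vector product of the transposed weight matrix.
#'
#' @param spikes binary vector of length `n_pre`.
#' @param array a `synapse_array`.
#' @return numeric vector of length `n_post` (normalized conductance units).
#' @export
weighted_sum <- function(spikes, array) {
  w <- read_weights(array)
  if (length(spikes) != nrow(w)) stop("spike vector length does not match array rows")
  as.vector(crossprod(w, spikes))
}

#' Transposed (backward) delta read gated by derivative bits
#'
#' Propagates the next layer's delta vector backward through the array and
#' gates the result with the 1-bit derivative flags:
#' `delta_i = kappa_bp * (sum_j delta_j W[i,j]) * deriv_bits_i`.
#'
#' @param delta_next delta vector of length `n_post` (volts).
#' @param deriv_bits binary vector of length `n_pre`.
#' @param array a `synapse_array`.
#' @param kappa_bp dimensionless backward gain (pulse-width modulation and
#'   integration constants collapsed into one scale).
#' @return delta vector of length `n_pre`.
#' @export
backward_sum <- function(delta_next, deriv_bits, array, kappa_bp = 1) {
  w <- read_weights(array)
  if (length(delta_next) != ncol(w)) stop("delta vector length does not match array columns")
  if (length(deriv_bits) != nrow(w)) stop("derivative bit length does not match array rows")
  kappa_bp * as.vector(w %*% delta_next) * deriv_bits
}

#' Crossbar update-phase bias scheme
#'
#' Voltage amplitudes applied to the bottom-gate (BG, row) and Schottky
#' (S, column) lines in the update phase, and the |V_BG - V_S| thresholds a
#' cell must see to be programmed or erased. With the defaults, a selected
#' row (+2 V BG for program, -2 V for erase) combined with a pulsed column
#' (-3.5 V program pulse / +5 V erase pulse) yields 5.5 V (program) or 7 V
#' (erase) across the cell -- exactly the update conditions -- while every
#' other row/column combination stays below threshold and is inhibited.
#'
#' @param v_s_program,v_s_erase S-line pulse amplitudes (V).
#' @param v_bg_selected_program,v_bg_selected_erase selected BG-line DC
#'   bias (V).
#' @param v_unselected unselected-line voltage (V).
#' @param program_threshold,erase_threshold required |V_BG - V_S| (V).
#' @return an object of class `bias_scheme`.
#' @export
bias_scheme <- function(v_s_program = -3.5, v_s_erase = 5,
                        v_bg_selected_program = 2, v_bg_selected_erase = -2,
                        v_unselected = 0,
                        program_threshold = 5.5, erase_threshold = 7) {
  stopifnot(program_threshold > 0, erase_threshold > 0)
  structure(list(v_s_program = v_s_program, v_s_erase = v_s_erase,
                 v_bg_selected_program = v_bg_selected_program,
                 v_bg_selected_erase = v_bg_selected_erase,
                 v_unselected = v_unselected,
                 program_threshold = program_threshold,
                 erase_threshold = erase_threshold),
            class = "bias_scheme")
}

#' Bias seen by one cell in the update phase
#'
#' @param scheme a [bias_scheme()].
#' @param row_selected is the cell's BG row selected (S(T) = 1)?
#' @param col_pulsed does the cell's S column carry the update pulse
#'   (delta != 0)?
#' @param pulse_kind `"program"` or `"erase"`.
#' @return list with `v_bg`, `v_s`, and logical `updates` (whether the cell
#'   sees a pulse and |V_BG - V_S| meets the threshold).
#' @export
cell_bias_table <- function(scheme, row_selected, col_pulsed,
                            pulse_kind = c("program", "erase")) {
  pulse_kind <- match.arg(pulse_kind)
  v_s <- if (col_pulsed) {
    if (pulse_kind == "program") scheme$v_s_program else scheme$v_s_erase
  } else scheme$v_unselected
  v_bg <- if (row_selected) {
    if (pulse_kind == "program") scheme$v_bg_selected_program else scheme$v_bg_selected_erase
  } else scheme$v_unselected
  thr <- if (pulse_kind == "program") scheme$program_threshold else scheme$erase_threshold
  list(v_bg = v_bg, v_s = v_s,
       updates = col_pulsed && abs(v_bg - v_s) >= thr)
}

#' Full 4-condition bias table for one pulse kind
#'
#' Enumerates the four row/column selection states of a cell during the
#' update phase; exactly one (selected row, pulsed column) should update.
#'
#' @inheritParams cell_bias_table
#' @return a data.frame with one row per condition.
#' @export
full_bias_table <- function(scheme = bias_scheme(),
                            pulse_kind = c("program", "erase")) {
  pulse_kind <- match.arg(pulse_kind)
  grid <- expand.grid(row_selected = c(TRUE, FALSE),
                      col_pulsed = c(TRUE, FALSE))
  rows <- lapply(seq_len(nrow(grid)), function(k) {
    b <- cell_bias_table(scheme, grid$row_selected[k], grid$col_pulsed[k],
                         pulse_kind)
    data.frame(row_selected = grid$row_selected[k],
               col_pulsed = grid$col_pulsed[k],
               v_bg = b$v_bg, v_s = b$v_s,
               v_diff = abs(b$v_bg - b$v_s), updates = b$updates)
  })
  do.call(rbind, rows)
}

#' Predicted updated-cell mask from the bias rule
#'
#' The set of cells the voltage-selectivity rule predicts will update when
#' the rows in `rows_selected` are selected and the columns in
#' `cols_pulsed` carry pulses.
#'
#' @param scheme a [bias_scheme()].
#' @param rows_selected,cols_pulsed logical vectors.
#' @param pulse_kind `"program"` or `"erase"`.
#' @return logical matrix.
#' @export
bias_update_mask <- function(scheme, rows_selected, cols_pulsed,
                             pulse_kind = c("program", "erase")) {
  pulse_kind <- match.arg(pulse_kind)
  m <- outer(rows_selected, cols_pulsed, function(r, cp) {
    mapply(function(ri, ci) cell_bias_table(scheme, ri, ci, pulse_kind)$updates,
           r, cp)
  })
  matrix(as.logical(m), length(rows_selected), length(cols_pulsed))
}

#' Per-pair pulse-width schedule for one update phase
#'
#' @param delta_t matrix of pulse widths (`>= 0`, time units). The same
#'   width drives both devices of a pair.
#' @param polarity integer matrix in `{-1, 0, 1}`: `+1` means the weight
#'   must grow (erase pulse on G+, program pulse on G-), `-1` the reverse,
#'   `0` no update. `delta_t` must be 0 wherever `polarity` is 0.
#' @return an object of class `update_schedule`.
#' @export
update_schedule <- function(delta_t, polarity) {
  stopifnot(all(dim(delta_t) == dim(polarity)))
  if (any(delta_t < 0)) stop("pulse widths must be non-negative")
  if (!all(polarity %in% c(-1, 0, 1))) stop("polarity must be in {-1, 0, 1}")
  if (any(delta_t[polarity == 0] != 0))
    stop("delta_t must be 0 where polarity is 'none'")
  structure(list(delta_t = delta_t, polarity = polarity),
            class = "update_schedule")
}

#' Parallel update of a synapse array
#'
#' Applies one update phase: for every pair with non-zero polarity, an
#' erase pulse of the scheduled width is applied to one device of the pair
#' and a program pulse of the same width to the other (erase on G+ /
#' program on G- when the weight grows, the reverse when it shrinks). All
#' pulses land in one parallel pass; pairs with zero width are untouched.
#' The set of touched cells equals the set predicted by the bias
#' selectivity rule ([bias_update_mask()]), which is asserted when
#' `check_bias = TRUE`.
#'
#' @param array a `synapse_array`.
#' @param schedule an [update_schedule()] matching the array's shape.
#' @param scheme a [bias_scheme()].
#' @param check_bias verify that the default bias rule selects exactly the
#'   scheduled cells.
#' @return the updated `synapse_array`.
#' @export
parallel_update <- function(array, schedule, scheme = bias_scheme(),
                            check_bias = TRUE) {
  w <- read_weights(array)
  stopifnot(all(dim(schedule$delta_t) == dim(w)))
  dt_pos <- schedule$delta_t * (schedule$polarity > 0)
  dt_neg <- schedule$delta_t * (schedule$polarity < 0)
  if (check_bias) {
    sched_mask <- schedule$delta_t > 0 & schedule$polarity != 0
    rows_sel <- rowSums(sched_mask) > 0
    cols_pul <- colSums(sched_mask) > 0
    pred <- bias_update_mask(scheme, rows_sel, cols_pul, "program") &
      bias_update_mask(scheme, rows_sel, cols_pul, "erase")
    # the bias rule updates the full selected-rows x pulsed-columns
    # rectangle; a schedule must not pulse outside it
    if (any(sched_mask & !pred))
      stop("schedule pulses a cell the bias rule would inhibit")
  }
  array$g_plus  <- apply_pulse(array$g_plus,  "erase",   dt_pos)
  array$g_plus  <- apply_pulse(array$g_plus,  "program", dt_neg)
  array$g_minus <- apply_pulse(array$g_minus, "program", dt_pos)
  array$g_minus <- apply_pulse(array$g_minus, "erase",   dt_neg)
  array
}
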