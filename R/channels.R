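# Electrode montage: 64 extended-10/20 labels with approximate 2-D scalp
# positions. Positions are schematic (row = anterior-posterior band, column =
# lateral index); they only drive distance-decaying noise covariance and
# topography weights, not source modelling.

montage_rows <- list(
  Fp = list(y = 0.95, labels = c("Fp1", "Fp2")),
  AF = list(y = 0.75, labels = c("AF7", "AF3", "AF4", "AF8")),
  F  = list(y = 0.55, labels = c("F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8")),
  FC = list(y = 0.30, labels = c("FT9", "FT7", "FC5", "FC3", "FC1", "FC2", "FC4", "FC6", "FT8", "FT10")),
  C  = list(y = 0.00, labels = c("T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8")),
  CP = list(y = -0.30, labels = c("TP9", "TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8", "TP10")),
  P  = list(y = -0.55, labels = c("P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8")),
  PO = list(y = -0.75, labels = c("PO9", "PO7", "PO3", "POz", "PO4", "PO8", "PO10")),
  O  = list(y = -0.95, labels = c("O1", "Oz", "O2"))
)

label_x <- function(label) {
  suffix <- sub("^[A-Za-z]+", "", label)
  if (suffix == "z" || suffix == "") return(0)
  num <- as.integer(suffix)
  idx <- ceiling(num / 2)                # 1,2 -> 1; 3,4 -> 2; ...
  sgn <- if (num %% 2 == 1) -1 else 1    # odd = left hemisphere
  sgn * idx * 0.19
}

full_montage_tbl <- function() {
  rows <- purrr::map_dfr(montage_rows, function(r) {
    tibble(label = r$labels, y = r$y)
  })
  rows$x <- vapply(rows$label, label_x, numeric(1))
  rows[, c("label", "x", "y")]
}

# Priority order for reduced montages: the left-parietal cluster and a broad
# spread of sites come first so small simulated caps still carry the channels
# the ERP analysis averages over.
montage_priority <- c(
  "Pz", "P1", "P3", "P5", "Cz", "Fz", "Oz", "C3", "C4", "F3", "F4",
  "O1", "O2", "P2", "P4", "P6", "CPz", "POz", "CP3", "CP4", "FC1", "FC2"
)

#' Electrode montage used by the synthetic-data generator
#'
#' Returns `n_channels` extended-10/20 channel labels with schematic 2-D
#' positions. The full cap has 64 channels; reduced caps keep the
#' left-parietal cluster (`Pz`, `P1`, `P3`, `P5`) and a spatially spread
#' subset so downstream analyses remain well defined.
#'
#' @param n_channels Number of channels, between 4 and 64.
#' @return A tibble with columns `label`, `x`, `y`.
#' @export
#' @examples
#' channel_montage(8)
channel_montage <- function(n_channels = 64) {
  stopifnot(n_channels >= 4, n_channels <= 64)
  full <- full_montage_tbl()
  ord <- c(montage_priority, setdiff(full$label, montage_priority))
  keep <- ord[seq_len(n_channels)]
  out <- full[match(keep, full$label), ]
  tibble::as_tibble(out)
}

#' Default left-parietal electrode cluster
#'
#' The electrode cluster over which retrieval-phase ERPs are averaged when
#' testing the parietal old/new effect.
#'
#' @return Character vector of channel labels.
#' @export
parietal_cluster <- function() c("Pz", "P1", "P3", "P5")
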