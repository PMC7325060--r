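# Lesion geometry: the three-domain partition of the grid into an elliptical
# tumour, a cell-free tumour-bone margin (default one pixel thick) and the
# surrounding bone, plus irreversible bone digestion.

# grid sides used in the published size study, keyed by "a x b"
GRID_SIZE_TABLE <- c(
  "2x1" = 120L, "8x7" = 180L,
  "64x53" = 300L, "128x106" = 300L,
  "256x213" = 500L, "500x416" = 800L
)

#' Default grid side for a studied lesion size
#'
#' @param a_tumor,b_tumor Horizontal and vertical tumour axes in pixels.
#' @return The grid side N used in the size study for this lesion.
#' @export
#' @examples
#' default_grid_size(2, 1)     # 120
#' default_grid_size(256, 213) # 500
default_grid_size <- function(a_tumor, b_tumor) {
  key <- paste0(a_tumor, "x", b_tumor)
  if (!key %in% names(GRID_SIZE_TABLE)) {
    abort(sprintf(
      "no default grid size for lesion [%s]; supply `n` explicitly", key
    ))
  }
  unname(GRID_SIZE_TABLE[key])
}

#' Lesion configuration
#'
#' @param a_tumor,b_tumor Initial tumour axes in pixels (horizontal,
#'   vertical); `[a_tumor x b_tumor]` identifies the lesion.
#' @param n Grid side in pixels; defaults to the studied value for known
#'   lesion sizes (see [default_grid_size()]).
#' @param margin_thickness Initial thickness of the cell-free tumour-bone
#'   margin in pixels (default 1; the distance study uses 1, 5, 10, 15, 20).
#' @return A `lesion_config` object.
#' @export
lesion_config <- function(a_tumor, b_tumor, n = NULL,
                          margin_thickness = 1L) {
  if (a_tumor < 1 || b_tumor < 1) abort("tumour axes must be >= 1 pixel")
  if (margin_thickness < 1) abort("margin_thickness must be >= 1 pixel")
  if (is.null(n)) n <- default_grid_size(a_tumor, b_tumor)
  structure(
    list(
      a_tumor = as.integer(a_tumor), b_tumor = as.integer(b_tumor),
      n = as.integer(n), margin_thickness = as.integer(margin_thickness)
    ),
    class = "lesion_config"
  )
}

#' @export
print.lesion_config <- function(x, ...) {
  cat(sprintf(
    "<lesion_config> [%d x %d] on %d x %d grid, margin %d px\n",
    x$a_tumor, x$b_tumor, x$n, x$n, x$margin_thickness
  ))
  invisible(x)
}

new_lattice_state <- function(label, clock, time_h = 0L, status = "running",
                              config = NULL) {
  structure(
    list(label = label, clock = clock, time_h = as.integer(time_h),
         status = status, config = config),
    class = "lattice_state"
  )
}

state_label <- function(state) {
  if (inherits(state, "lattice_state")) state$label else state
}

#' Domain counts of a lattice state
#'
#' @param state A `lattice_state`.
#' @return A one-row tibble with `n_tumour`, `n_margin`, `n_bone`.
#' @export
state_counts <- function(state) {
  label <- state_label(state)
  tibble(
    n_tumour = sum(label == LBL_TUMOUR),
    n_margin = sum(label == LBL_MARGIN),
    n_bone = sum(label == LBL_BONE)
  )
}

#' @export
print.lattice_state <- function(x, ...) {
  cts <- state_counts(x)
  cat(sprintf(
    "<lattice_state> %d x %d grid at t = %d h (%s)\n  tumour %d | margin %d | bone %d\n",
    nrow(x$label), ncol(x$label), x$time_h, x$status,
    cts$n_tumour, cts$n_margin, cts$n_bone
  ))
  invisible(x)
}

#' @export
as_tibble.lattice_state <- function(x, ...) {
  label <- x$label
  n <- nrow(label)
  grid <- expand.grid(r = 0:(n - 1), q = 0:(n - 1))
  tibble(
    q = as.integer(grid$q), r = as.integer(grid$r),
    domain = factor(
      c("bone", "margin", "tumour")[as.vector(label) + 1L],
      levels = c("bone", "margin", "tumour")
    )
  )
}

# hex graph-distance dilation of a logical site mask by `steps` rings
dilate_mask <- function(mask, steps) {
  n <- nrow(mask)
  out <- mask
  frontier <- which(mask)
  for (s in seq_len(steps)) {
    if (length(frontier) == 0) break
    r0 <- (frontier - 1L) %% n
    q0 <- (frontier - 1L) %/% n
    nxt <- integer(0)
    for (k in seq_len(6)) {
      nq <- q0 + HEX_OFFSETS[k, "q"]
      nr <- r0 + HEX_OFFSETS[k, "r"]
      ok <- nq >= 0 & nq < n & nr >= 0 & nr < n
      idx <- nr[ok] + 1L + nq[ok] * n
      fresh <- idx[!out[idx]]
      out[fresh] <- TRUE
      nxt <- c(nxt, fresh)
    }
    frontier <- unique(nxt)
  }
  out
}

#' Initialize an osteolytic lesion
#'
#' Builds the three-domain lattice: tumour sites are those whose centroid
#' lies inside the centred ellipse with semi-axes `a_tumor / 2` and
#' `b_tumor / 2` (in centroid coordinates); the `[2 x 1]` lesion is exactly
#' two adjacent sites; the margin is every non-tumour site within
#' `margin_thickness` lattice steps of the tumour; everything else is bone.
#' Per-cell clocks are drawn uniformly from 1..24 hours.
#'
#' @param config A [lesion_config()].
#' @param seed Optional integer seed (sets R's RNG before drawing clocks).
#' @return A `lattice_state`.
#' @export
#' @examples
#' st <- initialize_lesion(lesion_config(2, 1), seed = 1)
#' state_counts(st)
initialize_lesion <- function(config, seed = NULL) {
  stopifnot(inherits(config, "lesion_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- config$n
  qv <- rep(0:(n - 1), each = n)
  rv <- rep(0:(n - 1), times = n)
  c0 <- n %/% 2
  # centroid coordinates in lattice units, relative to the central site
  x <- (qv + rv / 2) - (c0 + c0 / 2)
  y <- (sqrt(3) / 2) * (rv - c0)
  if (config$a_tumor == 2 && config$b_tumor == 1) {
    tumour <- (qv == c0 | qv == c0 + 1) & rv == c0
  } else {
    tumour <- (x / (config$a_tumor / 2))^2 + (y / (config$b_tumor / 2))^2 <= 1
  }
  tmask <- matrix(FALSE, n, n)
  tmask[cbind(rv + 1L, qv + 1L)] <- tumour
  if (!any(tmask)) abort("degenerate configuration: no tumour site inside the ellipse")
  lesion_mask <- dilate_mask(tmask, config$margin_thickness)
  label <- matrix(LBL_BONE, n, n)
  label[lesion_mask] <- LBL_MARGIN
  label[tmask] <- LBL_TUMOUR
  border <- c(label[1, ], label[n, ], label[, 1], label[, n])
  if (any(border != LBL_BONE)) {
    abort("initial tumour + margin touches the grid border; increase `n`")
  }
  clock <- matrix(-1L, n, n)
  clock[tmask] <- sample(1:24, sum(tmask), replace = TRUE)
  new_lattice_state(label, clock, config = config)
}

#' Digest the bone around a newly placed tumour cell
#'
#' Every bone neighbour of the cell becomes margin, re-establishing the
#' one-pixel minimum margin thickness. Digestion is irreversible and
#' idempotent.
#'
#' @param state A `lattice_state`.
#' @param q,r Axial coordinates of the placed tumour cell.
#' @return The updated `lattice_state`.
#' @export
digest_bone <- function(state, q, r) {
  stopifnot(inherits(state, "lattice_state"))
  label <- state$label
  if (label[r + 1L, q + 1L] != LBL_TUMOUR) {
    abort(sprintf("site (%d, %d) is not a tumour cell", q, r))
  }
  state$label <- cpp_digest(label, q, r)
  state
}

#' @export
autoplot.lattice_state <- function(object, ...) {
  df <- as_tibble(object)
  xy <- hex_centroid(df$q, df$r, delta = 1)
  df$x <- xy$x
  df$y <- xy$y
  df <- dplyr::filter(df, .data$domain != "bone")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, colour = .data$domain)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::scale_colour_manual(values = c(margin = "darkseagreen3", tumour = "goldenrod2")) +
    ggplot2::labs(x = "x (lattice units)", y = "y (lattice units)",
                  title = sprintf("lesion at t = %d h", object$time_h)) +
    ggplot2::theme_minimal()
}
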