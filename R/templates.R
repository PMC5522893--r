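#' Built-in landmark templates
#'
#' Returns one of the landmark templates shipped with the package: a 68-point
#' template describing the proximal femur and acetabulum on a hip DXA image, or
#' an 89-point template covering the vertebral bodies from T10 down to L5 on a
#' lateral spine DXA image.
#'
#' The shipped point coordinates are plausible hand-constructed outlines used as
#' mean shapes by the synthetic-cohort generator and for drawing; anatomical
#' point definitions on real images are a matter for the marking protocol, and
#' the labels here are best-effort bookkeeping only.
#'
#' @param name Template name, `"hip"` or `"spine"`.
#' @return An object of class `point_template`: a list with elements `name`,
#'   `n_points`, `labels` (character vector of length `n_points`),
#'   `outline_groups` (named list of point-index vectors used to draw connected
#'   outlines) and `points` (an `n_points` x 2 matrix of reference coordinates,
#'   image pixel convention: origin top-left, x rightward, y downward).
#' @examples
#' tpl <- builtin_template("hip")
#' tpl$n_points
#' @export
builtin_template <- function(name) {
  if (!is.character(name) || length(name) != 1L) {
    stop("`name` must be a single template name", call. = FALSE)
  }
  switch(name,
    hip = hip_template(),
    spine = spine_template(),
    stop(glue::glue("unknown template '{name}'; available: 'hip', 'spine'"),
      call. = FALSE
    )
  )
}

new_point_template <- function(name, points, labels, outline_groups) {
  stopifnot(nrow(points) >= 3L, length(labels) == nrow(points))
  stopifnot(all(unlist(outline_groups) >= 1L), all(unlist(outline_groups) <= nrow(points)))
  structure(
    list(
      name = name,
      n_points = nrow(points),
      labels = labels,
      outline_groups = outline_groups,
      points = unname(points)
    ),
    class = "point_template"
  )
}

#' @export
print.point_template <- function(x, ...) {
  cat(sprintf(
    "<point_template '%s': %d points, %d outline group(s)>\n",
    x$name, x$n_points, length(x$outline_groups)
  ))
  invisible(x)
}

# Resample an open polyline (control points, rows) to n points at equal
# arc-length spacing. Used only to build the shipped reference outlines.
resample_polyline <- function(ctrl, n) {
  seg <- sqrt(rowSums(diff(ctrl)^2))
  s <- c(0, cumsum(seg))
  t <- seq(0, s[length(s)], length.out = n)
  cbind(
    stats::approx(s, ctrl[, 1], xout = t)$y,
    stats::approx(s, ctrl[, 2], xout = t)$y
  )
}

# 68-point proximal femur + acetabulum outline on a nominal 300 x 252 px image.
# Points 1..54 trace the femur from the lateral shaft over the greater
# trochanter, femoral neck and head to the lesser trochanter and medial shaft;
# points 55..68 trace the acetabular rim/sourcil above the femoral head.
hip_template <- function() {
  femur_ctrl <- rbind(
    c(95, 245), c(92, 210), c(90, 180),          # lateral shaft
    c(86, 150), c(80, 128), c(84, 110),          # greater trochanter lateral
    c(95, 96), c(108, 92),                       # trochanter tip
    c(118, 100), c(126, 108),                    # intertrochanteric crest
    c(138, 96), c(150, 84), c(163, 74),          # superior neck
    c(176, 64), c(188, 57),                      # head-neck junction
    c(200, 52), c(214, 52), c(227, 58),          # superior head
    c(237, 68), c(243, 82), c(244, 97),          # medial head
    c(240, 111), c(231, 122),                    # inferior head
    c(219, 129), c(206, 133),                    # fovea region
    c(193, 139), c(181, 148), c(170, 158),       # inferior neck
    c(160, 170), c(152, 183),                    # calcar
    c(146, 196), c(143, 205),                    # lesser trochanter superior
    c(150, 212), c(152, 222),                    # lesser trochanter
    c(146, 231), c(140, 240), c(136, 249)        # medial shaft
  )
  acet_ctrl <- rbind(
    c(252, 36), c(240, 28), c(226, 22),          # lateral acetabular edge
    c(210, 18), c(194, 17), c(178, 20),          # sourcil
    c(164, 26), c(153, 35), c(146, 46)           # medial rim / teardrop
  )
  femur <- resample_polyline(femur_ctrl, 54)
  acet <- resample_polyline(acet_ctrl, 14)
  pts <- rbind(femur, acet)
  labels <- c(
    sprintf("femur_%02d", 1:54),
    sprintf("acetabulum_%02d", 1:14)
  )
  labels[7:10] <- sprintf("greater_trochanter_%02d", 1:4)
  labels[16:23] <- sprintf("femoral_head_%02d", 1:8)
  labels[31:34] <- sprintf("lesser_trochanter_%02d", 1:4)
  new_point_template(
    "hip", pts, labels,
    outline_groups = list(femur = 1:54, acetabulum = 55:68)
  )
}

# 89-point lumbar spine template, T10 down to L5, lateral view on a nominal
# 1200 x 400 px image (x is the anterior-posterior direction, y is caudal).
# Each of the 8 vertebral bodies contributes 11 points around its outline
# (4 corners plus edge midpoints); point 89 marks the sacral promontory.
spine_template <- function() {
  # centre-line of a gentle lordotic curve, T10 (top) to L5 (bottom)
  n_vert <- 8L
  yc <- seq(120, 1020, length.out = n_vert)
  xc <- 200 - 55 * sin((yc - 120) / 900 * pi) # anterior bow
  # vertebral bodies grow slightly caudally
  width <- seq(62, 78, length.out = n_vert) # a-p diameter
  height <- seq(52, 64, length.out = n_vert)
  tilt <- -cos((yc - 120) / 900 * pi) * 0.22 # radians, follows the curve
  vert <- function(i) {
    w <- width[i] / 2
    h <- height[i] / 2
    # 11 points: corners + edge midpoints, clockwise from antero-superior,
    # with an extra midpoint on each endplate (endplates matter most).
    base <- rbind(
      c(-w, -h), c(0, -h - 3), c(w, -h),      # superior endplate (3)
      c(w, 0),                                 # posterior wall mid (1)
      c(w, h), c(0, h + 3), c(-w, h),          # inferior endplate (3)
      c(-w, h / 2), c(-w, 0), c(-w, -h / 2),   # anterior wall (3)
      c(0, 0)                                  # body centre (1)
    )
    th <- tilt[i]
    rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    sweep(base %*% rot, 2, c(xc[i], yc[i]), `+`)
  }
  pts <- do.call(rbind, lapply(seq_len(n_vert), vert))
  pts <- rbind(pts, c(xc[n_vert] - width[n_vert] / 2 - 10, yc[n_vert] + 85))
  vnames <- c("T10", "T11", "T12", "L1", "L2", "L3", "L4", "L5")
  part <- c(
    "sup_ant", "sup_mid", "sup_post", "post_mid", "inf_post", "inf_mid",
    "inf_ant", "ant_lower", "ant_mid", "ant_upper", "centre"
  )
  labels <- c(
    as.vector(t(outer(vnames, part, paste, sep = "_"))),
    "sacral_promontory"
  )
  groups <- stats::setNames(
    lapply(seq_len(n_vert), function(i) ((i - 1L) * 11L + 1L):((i - 1L) * 11L + 10L)),
    vnames
  )
  new_point_template("spine", pts, labels, outline_groups = groups)
}
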