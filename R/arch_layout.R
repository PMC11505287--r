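# Parametric dental-arch layout shared by the synthetic jaw generator and the
# canonical landmark template. The arch midline is a parabola in the xy-plane,
# open toward -y, apex at (0, arch_depth), ends on y = 0. Teeth are placed by
# arc length, ordered L8..L1,R1..R8 from one end to the other.

# average adult mesiodistal crown widths / buccolingual depths (mm), positions 1..8
tooth_widths_default <- c(8.5, 6.6, 7.6, 7.0, 6.8, 10.0, 9.4, 8.8)
tooth_depths_default <- c(7.0, 6.2, 8.0, 9.0, 9.2, 11.0, 10.8, 10.4)

# per-tooth size table in arch order L8..L1,R1..R8
tooth_size_table <- function() {
  pos <- c(8:1, 1:8)
  data.frame(code = tooth_arch_order(), position = pos,
             width = tooth_widths_default[pos], depth = tooth_depths_default[pos])
}

arch_curve <- function(arch_width, arch_depth, n = 2048L) {
  t <- seq(-arch_width / 2, arch_width / 2, length.out = n)
  y <- arch_depth * (1 - (2 * t / arch_width)^2)
  seglen <- sqrt(diff(t)^2 + diff(y)^2)
  s <- c(0, cumsum(seglen))
  list(t = t, y = y, s = s, length = s[n])
}

# Evaluate arch position and unit tangent at arc length s (from the L8 end).
arch_point <- function(curve, s) {
  s <- pmin(pmax(s, 0), curve$length)
  x <- stats::approx(curve$s, curve$t, xout = s)$y
  hw <- max(curve$t)
  y <- max(curve$y) * (1 - (x / hw)^2)
  dydx <- -2 * max(curve$y) * x / hw^2
  tx <- 1 / sqrt(1 + dydx^2)
  cbind(x = x, y = y, tx = tx, ty = dydx * tx)
}

# Arc-length tooth centers for the given presence/width configuration.
# All 16 slots get a nominal center (missing teeth keep their slot so that
# neighbours do not shift); the leftover arch length is spread as equal gaps.
arch_slots <- function(arch_width, arch_depth, widths16, margin = 1.0) {
  curve <- arch_curve(arch_width, arch_depth)
  usable <- curve$length - 2 * margin
  gap <- (usable - sum(widths16)) / (length(widths16) - 1)
  cum <- margin + cumsum(c(0, widths16[-16] + gap)) + widths16 / 2
  p <- arch_point(curve, cum)
  list(centers = p[, c("x", "y"), drop = FALSE],
       tangents = p[, c("tx", "ty"), drop = FALSE],
       gap = gap, curve = curve)
}
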