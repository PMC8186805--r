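## Virtual 10-10 / 10-5 optode montage construction on a scalp surface.
##
## The 81-position 10-10 set is built from seven cranial fiducials by
## proportional arc-length subdivision of fiducial-anchored curves:
## the sagittal curve Nz-Vz-Iz, the coronal curve LPA-Vz-RPA, the outer
## ring through Nz/LPA/Iz/RPA, the circumferential ring through
## Fpz/T7/Oz/T8, and six transverse rows (AF, F, FC, CP, P, PO) spanning
## the circumferential ring across the sagittal curve.  The 10-5 set
## (358 positions including the 81) refines every curve at half spacing
## and adds eight intermediate transverse rows, an intermediate lateral
## ring between the outer and circumferential rings, and a mastoid arc
## (LMa to RMa around the occiput).  The enumeration is shipped as a
## fixed table so the montage sizes are forced by construction.

# Combinatorial (row, col) coordinates of the 81 positions on the
# schematic 11 x 11 montage grid.  Rows run Nz..Iz front to back, columns
# left outer ring .. right outer ring.
ten10_grid <- function() {
  g <- rbind(
    c("N1", 0, 0), c("Nz", 0, 5), c("N2", 0, 10),
    c("Fp1", 1, 1), c("Fpz", 1, 5), c("Fp2", 1, 9),
    cbind(c("AF9", "AF7", "AF3", "AFz", "AF4", "AF8", "AF10"), 2, c(0, 1, 3, 5, 7, 9, 10)),
    cbind(c("F9", "F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8", "F10"), 3, 0:10),
    cbind(c("FT9", "FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6", "FT8", "FT10"), 4, 0:10),
    cbind(c("T9", "T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8", "T10"), 5, 0:10),
    cbind(c("TP9", "TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8", "TP10"), 6, 0:10),
    cbind(c("P9", "P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8", "P10"), 7, 0:10),
    cbind(c("PO9", "PO7", "PO3", "POz", "PO4", "PO8", "PO10"), 8, c(0, 1, 3, 5, 7, 9, 10)),
    c("O1", 9, 1), c("Oz", 9, 5), c("O2", 9, 9),
    c("I1", 10, 0), c("Iz", 10, 5), c("I2", 10, 10))
  data.frame(label = g[, 1], row = as.integer(g[, 2]), col = as.integer(g[, 3]),
             stringsAsFactors = FALSE)
}

# 10-10 label sequences of the construction curves (montage order)
montage_curves <- function() {
  list(
    sagittal = list(labels = c("Nz", "Fpz", "AFz", "Fz", "FCz", "Cz", "CPz",
                               "Pz", "POz", "Oz", "Iz"), closed = FALSE),
    coronal = list(labels = c("T9", "T7", "C5", "C3", "C1", "Cz", "C2", "C4",
                              "C6", "T8", "T10"), closed = FALSE),
    ring = list(labels = c("Nz", "N1", "AF9", "F9", "FT9", "T9", "TP9", "P9",
                           "PO9", "I1", "Iz", "I2", "PO10", "P10", "TP10",
                           "T10", "FT10", "F10", "AF10", "N2"), closed = TRUE),
    circ = list(labels = c("Fpz", "Fp1", "AF7", "F7", "FT7", "T7", "TP7", "P7",
                           "PO7", "O1", "Oz", "O2", "PO8", "P8", "TP8", "T8",
                           "FT8", "F8", "AF8", "Fp2"), closed = TRUE),
    AF = list(labels = c("AF7", "AF3", "AFz", "AF4", "AF8"), closed = FALSE),
    F  = list(labels = c("F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8"), closed = FALSE),
    FC = list(labels = c("FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6", "FT8"), closed = FALSE),
    CP = list(labels = c("TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8"), closed = FALSE),
    P  = list(labels = c("P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8"), closed = FALSE),
    PO = list(labels = c("PO7", "PO3", "POz", "PO4", "PO8"), closed = FALSE)
  )
}

# transverse row level (half-grid R) per row curve, and intermediate rows
row_levels <- function() c(AF = 4L, F = 6L, FC = 8L, CP = 12L, P = 14L, PO = 16L)
intermediate_levels <- function() {
  c(AFp = 3L, AFF = 5L, FFC = 7L, FCC = 9L, CCP = 11L, CPP = 13L,
    PPO = 15L, POO = 17L)
}

sagittal_ten5_labels <- function() {
  c("Nz", "NFpz", "Fpz", "AFpz", "AFz", "AFFz", "Fz", "FFCz", "FCz", "FCCz",
    "Cz", "CCPz", "CPz", "CPPz", "Pz", "PPOz", "POz", "POOz", "Oz", "OIz", "Iz")
}
coronal_ten5_labels <- function() {
  c("T9", "T9h", "T7", "T7h", "C5", "C5h", "C3", "C3h", "C1", "C1h", "Cz",
    "C2h", "C2", "C4h", "C4", "C6h", "C6", "T8h", "T8", "T10h", "T10")
}

#' Construct the 81-position 10-10 montage
#'
#' Builds the standard construction curves from the seven fiducials and
#' places virtual optodes at 10%/20% proportional arc-length subdivisions:
#' the sagittal curve Nz-Vz-Iz (11 positions), the coronal curve
#' LPA-Vz-RPA (10 more), the closed outer ring through the four
#' horizontal fiducials (16 more), the closed circumferential ring
#' through Fpz, T7, Oz, T8 (16 more) and six transverse rows spanning the
#' circumferential ring (28 more): 81 labeled positions in total.
#'
#' @param surface a `scalp_surface`.
#' @param fiducials data frame with columns `name, x, y, z` containing
#'   Nz, Iz, Vz, LPA, RPA, LMa, RMa (mm, on or near the scalp surface).
#' @return An object of class `montage` with elements `optodes`
#'   (data frame: label, tier, index, x, y, z), `surface`, `fiducial_idx`,
#'   `tier` (`"10-10"`).
#' @export
construct_10_10 <- function(surface, fiducials) {
  stopifnot(inherits(surface, "scalp_surface"))
  need <- c("Nz", "Iz", "Vz", "LPA", "RPA", "LMa", "RMa")
  miss <- setdiff(need, fiducials$name)
  if (length(miss)) stop("missing fiducial(s): ", paste(miss, collapse = ", "))
  fmat <- as.matrix(fiducials[match(need, fiducials$name), c("x", "y", "z")])
  # fiducials must lie on the scalp (within half a voxel of the surface)
  fidx <- surface_nearest(surface, fmat)
  off <- sqrt(rowSums((surface$points[fidx, , drop = FALSE] - fmat)^2))
  if (any(off > surface$voxel_size)) {
    stop("fiducial(s) off the scalp surface: ",
         paste(need[off > surface$voxel_size], collapse = ", "))
  }
  names(fidx) <- need

  pos <- integer(0)  # label -> surface point index
  place <- function(path, fracs, labels) {
    idx <- path_point_at(path, fracs, surface)
    names(idx) <- labels
    pos <<- c(pos, idx)
  }

  sag <- geodesic_polyline(surface, fidx[c("Nz", "Vz", "Iz")])
  place(sag, seq(0, 1, by = 0.1), montage_curves()$sagittal$labels)

  cor <- geodesic_polyline(surface, fidx[c("LPA", "Vz", "RPA")])
  cor_lab <- montage_curves()$coronal$labels
  place(cor, seq(0, 1, by = 0.1)[-6], cor_lab[-6])  # Cz comes from the sagittal curve

  # outer ring, one half at a time so T9/T10 pin to the preauricular points
  ringL <- geodesic_polyline(surface, fidx[c("Nz", "LPA", "Iz")])
  place(ringL, seq(0.1, 0.9, by = 0.1)[-5],
        c("N1", "AF9", "F9", "FT9", "TP9", "P9", "PO9", "I1"))
  ringR <- geodesic_polyline(surface, fidx[c("Nz", "RPA", "Iz")])
  place(ringR, seq(0.1, 0.9, by = 0.1)[-5],
        c("N2", "AF10", "F10", "FT10", "TP10", "P10", "PO10", "I2"))

  circL <- geodesic_polyline(surface, c(pos["Fpz"], pos["T7"], pos["Oz"]))
  place(circL, seq(0.1, 0.9, by = 0.1)[-5],
        c("Fp1", "AF7", "F7", "FT7", "TP7", "P7", "PO7", "O1"))
  circR <- geodesic_polyline(surface, c(pos["Fpz"], pos["T8"], pos["Oz"]))
  place(circR, seq(0.1, 0.9, by = 0.1)[-5],
        c("Fp2", "AF8", "F8", "FT8", "TP8", "P8", "PO8", "O2"))

  rows <- list(
    AF = list(ends = c("AF7", "AFz", "AF8"), k = c(4, 12), lab = c("AF3", "AF4")),
    F  = list(ends = c("F7", "Fz", "F8"), k = c(2, 4, 6, 10, 12, 14),
              lab = c("F5", "F3", "F1", "F2", "F4", "F6")),
    FC = list(ends = c("FT7", "FCz", "FT8"), k = c(2, 4, 6, 10, 12, 14),
              lab = c("FC5", "FC3", "FC1", "FC2", "FC4", "FC6")),
    CP = list(ends = c("TP7", "CPz", "TP8"), k = c(2, 4, 6, 10, 12, 14),
              lab = c("CP5", "CP3", "CP1", "CP2", "CP4", "CP6")),
    P  = list(ends = c("P7", "Pz", "P8"), k = c(2, 4, 6, 10, 12, 14),
              lab = c("P5", "P3", "P1", "P2", "P4", "P6")),
    PO = list(ends = c("PO7", "POz", "PO8"), k = c(4, 12), lab = c("PO3", "PO4"))
  )
  for (rw in rows) {
    path <- geodesic_polyline(surface, pos[rw$ends])
    place(path, rw$k / 16, rw$lab)
  }

  grid <- ten10_grid()
  pos <- pos[grid$label]
  optodes <- data.frame(label = grid$label, tier = "10-10",
                        index = as.integer(pos),
                        x = surface$points[pos, 1],
                        y = surface$points[pos, 2],
                        z = surface$points[pos, 3],
                        R = 2L * grid$row, C = 2L * grid$col,
                        stringsAsFactors = FALSE)
  structure(list(optodes = optodes, surface = surface, fiducial_idx = fidx,
                 tier = "10-10"),
            class = "montage")
}

#' Refine a 10-10 montage to the 358-position 10-5 set
#'
#' Subdivides every construction curve at half spacing (on-surface
#' geodesic midpoints between curve-adjacent positions) and adds the
#' structures that only exist at 10-5 resolution: eight intermediate
#' transverse rows, an intermediate lateral ring between the outer and
#' circumferential rings, and a 13-position mastoid arc from LMa to RMa
#' around the occiput.  All 81 parent positions are retained; the total
#' is 358 distinct positions.
#'
#' @param surface a `scalp_surface` (the one the montage was built on).
#' @param ten_ten a `montage` from [construct_10_10()].
#' @return A `montage` with `tier = "10-5"`, curve sequence tables and a
#'   half-grid registry used for channel construction.
#' @export
construct_10_5 <- function(surface, ten_ten) {
  stopifnot(inherits(ten_ten, "montage"))
  if (nrow(ten_ten$optodes) != 81L) {
    stop("construct_10_5 requires the 81-position 10-10 montage, got ",
         nrow(ten_ten$optodes), " positions")
  }
  fidx <- ten_ten$fiducial_idx
  pos <- stats::setNames(ten_ten$optodes$index, ten_ten$optodes$label)
  new_pos <- integer(0)
  place <- function(path, fracs, labels) {
    idx <- path_point_at(path, fracs, surface)
    names(idx) <- labels
    new_pos <<- c(new_pos, idx)
  }
  # half-grid registry: label -> (R, C) on the 21 x 21 schematic grid
  reg <- data.frame(label = ten_ten$optodes$label, R = ten_ten$optodes$R,
                    C = ten_ten$optodes$C, stringsAsFactors = FALSE)
  add_reg <- function(labels, R, C) {
    reg <<- rbind(reg, data.frame(label = labels, R = as.integer(R),
                                  C = as.integer(C), stringsAsFactors = FALSE))
  }

  sag <- geodesic_polyline(surface, fidx[c("Nz", "Vz", "Iz")])
  sag5 <- sagittal_ten5_labels()
  place(sag, seq(1, 19, by = 2) / 20, sag5[seq(2, 20, by = 2)])
  add_reg(sag5[seq(2, 20, by = 2)], R = seq(1, 19, by = 2), C = 10L)

  cor <- geodesic_polyline(surface, fidx[c("LPA", "Vz", "RPA")])
  cor5 <- coronal_ten5_labels()
  place(cor, seq(1, 19, by = 2) / 20, cor5[seq(2, 20, by = 2)])
  add_reg(cor5[seq(2, 20, by = 2)], R = 10L, C = seq(1, 19, by = 2))

  # closed rings: insert the geodesic midpoint of each adjacent pair
  mid_label <- function(a, b) paste0(a, "-", b)
  ring_seq <- local({
    lab <- montage_curves()$ring$labels
    out <- character(0)
    for (i in seq_along(lab)) {
      nxt <- lab[if (i == length(lab)) 1 else i + 1]
      out <- c(out, lab[i], mid_label(lab[i], nxt))
    }
    out
  })
  circ_seq <- local({
    lab <- montage_curves()$circ$labels
    out <- character(0)
    for (i in seq_along(lab)) {
      nxt <- lab[if (i == length(lab)) 1 else i + 1]
      out <- c(out, lab[i], mid_label(lab[i], nxt))
    }
    out
  })
  for (s in list(list(seq = ring_seq), list(seq = circ_seq))) {
    lab <- s$seq
    for (i in seq(2, length(lab), by = 2)) {
      a <- lab[i - 1]; b <- lab[if (i == length(lab)) 1 else i + 1]
      leg <- geodesic_path(surface, pos[a], pos[b])
      place(leg, 0.5, lab[i])
    }
  }

  # transverse rows at half spacing (17 slots between circumferential anchors)
  lev <- row_levels()
  rows <- list(
    AF = c("AF7", "AFz", "AF8"), F = c("F7", "Fz", "F8"),
    FC = c("FT7", "FCz", "FT8"), CP = c("TP7", "CPz", "TP8"),
    P = c("P7", "Pz", "P8"), PO = c("PO7", "POz", "PO8"))
  occupied <- list(AF = c(0, 4, 8, 12, 16), F = seq(0, 16, 2), FC = seq(0, 16, 2),
                   CP = seq(0, 16, 2), P = seq(0, 16, 2), PO = c(0, 4, 8, 12, 16))
  for (nm in names(rows)) {
    path <- geodesic_polyline(surface, pos[rows[[nm]]])
    k_new <- setdiff(0:16, occupied[[nm]])
    labs <- sprintf("%s_%d", nm, k_new)
    place(path, k_new / 16, labs)
    add_reg(labs, R = lev[[nm]], C = k_new + 2L)
  }

  pos <- c(pos, new_pos)

  # intermediate transverse rows between circ anchors via the sagittal curve
  ilev <- intermediate_levels()
  ianchors <- list(
    AFp = c("Fp1-AF7", "AFpz", "AF8-Fp2"),
    AFF = c("AF7-F7", "AFFz", "F8-AF8"),
    FFC = c("F7-FT7", "FFCz", "FT8-F8"),
    FCC = c("FT7-T7", "FCCz", "T8-FT8"),
    CCP = c("T7-TP7", "CCPz", "TP8-T8"),
    CPP = c("TP7-P7", "CPPz", "P8-TP8"),
    PPO = c("P7-PO7", "PPOz", "PO8-P8"),
    POO = c("PO7-O1", "POOz", "O2-PO8"))
  new_pos <- integer(0)
  for (nm in names(ianchors)) {
    path <- geodesic_polyline(surface, pos[ianchors[[nm]]])
    k_new <- setdiff(1:15, 8L)
    labs <- sprintf("%s_%d", nm, k_new)
    place(path, k_new / 16, labs)
    add_reg(labs, R = ilev[[nm]], C = k_new + 2L)
    # anchors enter the registry so oblique channels can resolve them
    add_reg(ianchors[[nm]], R = ilev[[nm]], C = c(2L, 10L, 18L))
  }

  # intermediate lateral ring between the outer and circumferential rings
  for (half in list(c("NFpz", "T9h", "OIz"), c("OIz", "T10h", "NFpz"))) {
    path <- geodesic_polyline(surface, pos[half])
    k_new <- setdiff(1:19, 10L)
    side <- if (half[2] == "T9h") "iL" else "iR"
    labs <- sprintf("%s_%d", side, k_new)
    place(path, k_new / 20, labs)
    # band levels align with the outer-ring slot levels front-to-back
    add_reg(labs, R = if (side == "iL") k_new else 20L - k_new,
            C = if (side == "iL") 1L else 19L)
  }

  # mastoid arc: LMa -> sub-inion -> RMa around the occiput
  viz <- geodesic_polyline(surface, fidx[c("Vz", "Iz")])
  npt <- nrow(viz$points)
  tangent <- viz$points[npt, ] - viz$points[max(1, npt - 3), ]
  tangent <- tangent / sqrt(sum(tangent^2))
  sub_iz <- surface_nearest(surface, viz$points[npt, ] + 10 * tangent)
  arc <- geodesic_polyline(surface, c(fidx["LMa"], sub_iz, fidx["RMa"]))
  place(arc, (0:12) / 12, c("LMa", sprintf("ma_%d", 1:11), "RMa"))

  pos <- c(pos, new_pos)
  if (anyDuplicated(pos)) {
    dup <- names(pos)[duplicated(pos) | duplicated(pos, fromLast = TRUE)]
    stop("montage positions collide on the discrete surface (",
         paste(unique(dup), collapse = ", "),
         "); use a finer voxel grid or a larger phantom")
  }

  parents <- ten_ten$optodes$label
  lab_all <- names(pos)
  ridx <- match(lab_all, reg$label)
  optodes <- data.frame(
    label = lab_all,
    tier = ifelse(lab_all %in% parents, "10-10", "10-5"),
    index = as.integer(pos),
    x = surface$points[pos, 1], y = surface$points[pos, 2],
    z = surface$points[pos, 3],
    R = ifelse(is.na(ridx), NA_integer_, reg$R[ridx]),
    C = ifelse(is.na(ridx), NA_integer_, reg$C[ridx]),
    stringsAsFactors = FALSE)
  structure(list(optodes = optodes, surface = surface, fiducial_idx = fidx,
                 tier = "10-5",
                 curve_seqs = list(sagittal = sag5, coronal = cor5,
                                   ring = ring_seq, circ = circ_seq),
                 registry = reg),
            class = "montage")
}

#' @export
print.montage <- function(x, ...) {
  cat(sprintf("%s montage: %d optodes\n", x$tier, nrow(x$optodes)))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Channel construction

# All flanking-pair combinations around 10-10 centres: along each
# construction curve, along the six meridional chains, and along the
# oblique (unit-diagonal and knight) chains of the montage grid; the
# three combinations centred on the nasion and preauricular fiducial
# positions are excluded (their pairs span the face and the ears).
straddle_table <- function() {
  grid <- ten10_grid()
  key <- function(r, c) paste(r, c, sep = ",")
  occ <- stats::setNames(grid$label, key(grid$row, grid$col))
  out <- list()
  add <- function(center, a, b, kind) {
    out[[length(out) + 1L]] <<- data.frame(center = center, a = a, b = b,
                                           kind = kind, stringsAsFactors = FALSE)
  }
  # (a) construction curves (10-10 members, nearest 10-10 on either side)
  for (nm in names(montage_curves())) {
    cv <- montage_curves()[[nm]]
    lab <- cv$labels; n <- length(lab)
    ii <- if (cv$closed) seq_len(n) else seq(2, n - 1)
    for (i in ii) {
      a <- lab[if (i == 1) n else i - 1]
      b <- lab[if (i == n) 1 else i + 1]
      add(lab[i], a, b, paste0("curve:", nm))
    }
  }
  # (b) meridional chains (within the region enclosed by the circ ring)
  chains <- list(c("F5", "FC5", "C5", "CP5", "P5"),
                 c("AF3", "F3", "FC3", "C3", "CP3", "P3", "PO3"),
                 c("F1", "FC1", "C1", "CP1", "P1"),
                 c("F2", "FC2", "C2", "CP2", "P2"),
                 c("AF4", "F4", "FC4", "C4", "CP4", "P4", "PO4"),
                 c("F6", "FC6", "C6", "CP6", "P6"))
  for (ch in chains) {
    for (i in seq(2, length(ch) - 1)) add(ch[i], ch[i - 1], ch[i + 1], "meridional")
  }
  # (c) oblique chains: unit diagonals and knight (1,2) steps on the grid
  dirs <- rbind(c(1, 1), c(1, -1), c(1, 2), c(1, -2))
  for (d in seq_len(nrow(dirs))) {
    dr <- dirs[d, 1]; dc <- dirs[d, 2]
    for (i in seq_len(nrow(grid))) {
      a <- occ[key(grid$row[i] - dr, grid$col[i] - dc)]
      b <- occ[key(grid$row[i] + dr, grid$col[i] + dc)]
      if (!is.na(a) && !is.na(b)) {
        add(grid$label[i], unname(a), unname(b),
            if (abs(dc) == 1) "diagonal" else "oblique")
      }
    }
  }
  tab <- do.call(rbind, out)
  tab <- tab[!tab$center %in% c("Nz", "T9", "T10"), ]
  rownames(tab) <- NULL
  tab
}

# resolve the 10-5-tier arm labels for one straddle
ten5_arms <- function(straddle, montage) {
  reg <- montage$registry
  regkey <- stats::setNames(reg$label, paste(reg$R, reg$C, sep = ","))
  gr <- ten10_grid()
  g_at <- function(lab) {
    i <- match(lab, gr$label)
    c(2L * gr$row[i], 2L * gr$col[i])
  }
  seqs <- c(montage$curve_seqs,
            list(AF = row_seq(montage, "AF"), F = row_seq(montage, "F"),
                 FC = row_seq(montage, "FC"), CP = row_seq(montage, "CP"),
                 P = row_seq(montage, "P"), PO = row_seq(montage, "PO")))
  kind <- straddle$kind
  if (startsWith(kind, "curve:")) {
    nm <- sub("curve:", "", kind)
    sq <- seqs[[nm]]
    n <- length(sq)
    i <- match(straddle$center, sq)
    closed <- nm %in% c("ring", "circ")
    a <- if (i == 1) { if (closed) sq[n] else NA } else sq[i - 1]
    b <- if (i == n) { if (closed) sq[1] else NA } else sq[i + 1]
    return(c(a, b))
  }
  X <- g_at(straddle$center); A <- g_at(straddle$a)
  d <- (A - X) / 2L   # half-grid step toward arm a
  c(unname(regkey[paste(X[1] + d[1], X[2] + d[2], sep = ",")]),
    unname(regkey[paste(X[1] - d[1], X[2] - d[2], sep = ",")]))
}

# full 10-5 sequence of a transverse row
row_seq <- function(montage, nm) {
  occ <- list(AF = c(0, 4, 8, 12, 16), F = seq(0, 16, 2), FC = seq(0, 16, 2),
              CP = seq(0, 16, 2), P = seq(0, 16, 2), PO = c(0, 4, 8, 12, 16))[[nm]]
  ten10 <- montage_curves()[[nm]]$labels
  out <- character(17)
  out[occ + 1] <- ten10
  k_new <- setdiff(0:16, occ)
  out[k_new + 1] <- sprintf("%s_%d", nm, k_new)
  out
}

#' Source-detector channels centred on 10-10 positions
#'
#' For every 10-10 electrode location, emits the channels whose two
#' member optodes straddle it symmetrically along a construction curve,
#' a meridional chain or an oblique chain of the montage: at the
#' `"10-10"` tier the flanking pair are the adjacent 10-10 electrodes on
#' either side; at the `"10-5"` tier they are the adjacent 10-5
#' electrodes.  The channel's scalp path is traced through its centring
#' electrode, so the path midpoint coincides with the 10-10 location up
#' to the equidistance of the two arms (checked against `tolerance`).
#'
#' @param montage a 10-5 `montage` from [construct_10_5()].
#' @param tier `"10-10"` or `"10-5"`.
#' @param tolerance optional maximum midpoint-to-centre offset in mm;
#'   channels exceeding it are dropped with a warning.  By default no
#'   filter is applied: every channel records its `midpoint_offset_mm`
#'   (half the difference of the two arm lengths), which quantifies how
#'   far the montage's combinatorial centring deviates from geometric
#'   centring on the given head.
#' @return A channel data frame: source, detector, center, kind,
#'   path_mm, separation_mm, midpoint_offset_mm, channel x/y/z.
#' @export
centered_adjacent_channels <- function(montage, tier = c("10-10", "10-5"),
                                       tolerance = NULL) {
  tier <- match.arg(tier)
  if (!identical(montage$tier, "10-5")) {
    stop("the full 10-5 montage is required (run construct_10_5 first)")
  }
  tab <- straddle_table()
  if (tier == "10-5") {
    arms <- t(vapply(seq_len(nrow(tab)),
                     function(i) ten5_arms(tab[i, ], montage), character(2)))
    tab$a <- arms[, 1]; tab$b <- arms[, 2]
    if (anyNA(tab$a) || anyNA(tab$b)) {
      stop("unresolved 10-5 arm(s) for centre(s): ",
           paste(tab$center[is.na(tab$a) | is.na(tab$b)], collapse = ", "))
    }
  }
  pos <- stats::setNames(montage$optodes$index, montage$optodes$label)
  centers <- unique(tab$center)
  d_arm <- matrix(NA_real_, nrow(tab), 2)
  for (ct in centers) {
    rows <- which(tab$center == ct)
    arm_lab <- unique(c(tab$a[rows], tab$b[rows]))
    dd <- surface_distances(montage$surface, pos[ct], pos[arm_lab])
    d_arm[rows, 1] <- dd[1, match(tab$a[rows], arm_lab)]
    d_arm[rows, 2] <- dd[1, match(tab$b[rows], arm_lab)]
  }
  path_mm <- d_arm[, 1] + d_arm[, 2]
  offset <- abs(d_arm[, 1] - d_arm[, 2]) / 2
  swap <- tab$a > tab$b   # deterministic source/detector order
  src <- ifelse(swap, tab$b, tab$a)
  det <- ifelse(swap, tab$a, tab$b)
  ctr_idx <- pos[tab$center]
  out <- data.frame(source = src, detector = det, center = tab$center,
                    kind = tab$kind, tier = tier, path_mm = path_mm,
                    separation_mm = path_mm,
                    midpoint_offset_mm = offset,
                    channel_x = montage$surface$points[ctr_idx, 1],
                    channel_y = montage$surface$points[ctr_idx, 2],
                    channel_z = montage$surface$points[ctr_idx, 3],
                    stringsAsFactors = FALSE)
  if (!is.null(tolerance)) {
    bad <- out$midpoint_offset_mm > tolerance
    if (any(bad)) {
      warning(sum(bad), " channel(s) dropped: midpoint offset exceeds ",
              signif(tolerance, 3), " mm")
      out <- out[!bad, ]
    }
  }
  out[order(out$source, out$detector), ]
}

#' Enumerate all unordered optode pairs as channels
#'
#' Traces the scalp geodesic between every pair of optodes, recording the
#' path length and the channel location at the path's halfway point.
#' By default the source-detector separation distance is the full scalp
#' path length; `separation = "half"` preserves the alternative reading
#' (half the path length).
#'
#' @param montage a `montage` (any tier), or a data frame of optodes with
#'   columns `label` and `index` plus a `surface`.
#' @param surface the `scalp_surface` (taken from the montage if absent).
#' @param separation `"full"` or `"half"`.
#' @return A channel data frame: source, detector, path_mm,
#'   separation_mm, channel x/y/z; one row per unordered pair.
#' @export
enumerate_all_pairs <- function(montage, surface = NULL,
                                separation = c("full", "half")) {
  separation <- match.arg(separation)
  if (inherits(montage, "montage")) {
    optodes <- montage$optodes
    surface <- montage$surface
  } else optodes <- montage
  if (is.null(surface)) stop("a scalp_surface is required")
  n <- nrow(optodes)
  if (n < 2) stop("need at least two optodes")
  if (anyDuplicated(optodes$index)) {
    d <- which(duplicated(optodes$index) | duplicated(optodes$index, fromLast = TRUE))
    stop("duplicate optode positions: ",
         paste(optodes$label[d], collapse = ", "))
  }
  idx <- optodes$index
  res <- vector("list", n - 1)
  for (i in seq_len(n - 1)) {
    targets <- idx[(i + 1):n]
    sp <- igraph::shortest_paths(surface$graph, from = idx[i], to = targets,
                                 mode = "all", output = "vpath")
    m <- length(targets)
    plen <- numeric(m); mid <- matrix(NA_real_, m, 3)
    for (q in seq_len(m)) {
      vp <- as.integer(sp$vpath[[q]])
      pts <- surface$points[vp, , drop = FALSE]
      if (nrow(pts) == 1) { plen[q] <- 0; mid[q, ] <- pts[1, ]; next }
      seg <- sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2))
      cum <- c(0, cumsum(seg))
      plen[q] <- cum[length(cum)]
      # channel location: the exact halfway point on the path polyline
      half <- plen[q] / 2
      j <- findInterval(half, cum, rightmost.closed = TRUE)
      j <- min(max(j, 1L), nrow(pts) - 1L)
      a <- if (cum[j + 1] > cum[j]) (half - cum[j]) / (cum[j + 1] - cum[j]) else 0
      mid[q, ] <- (1 - a) * pts[j, ] + a * pts[j + 1, ]
    }
    res[[i]] <- data.frame(source = optodes$label[i],
                           detector = optodes$label[(i + 1):n],
                           path_mm = plen,
                           channel_x = mid[, 1], channel_y = mid[, 2],
                           channel_z = mid[, 3], stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  out$separation_mm <- if (separation == "half") out$path_mm / 2 else out$path_mm
  rownames(out) <- NULL
  out
}

#' Select channels near a target separation distance
#'
#' @param channels a channel data frame with a `separation_mm` column.
#' @param target target separation in mm, one of 10, 15, ..., 60.
#' @param window half-width of the acceptance window in mm.
#' @return The selected channels, ordered by (source, detector).  An
#'   empty selection triggers a warning (not an error).
#' @export
select_by_target_separation <- function(channels, target, window = 2.5) {
  if (!target %in% seq(10, 60, by = 5)) {
    stop("target separation must be one of 10, 15, ..., 60 mm")
  }
  if (window <= 0) stop("window must be positive")
  sel <- channels[abs(channels$separation_mm - target) <= window, ]
  if (nrow(sel) == 0) warning("no channels within ", window, " mm of ", target, " mm")
  sel[order(sel$source, sel$detector), ]
}

#' Export / import optode tables as CSV
#'
#' @param montage a `montage` (write) or CSV path (read).
#' @param path CSV path.
#' @return The optode data frame (read) or `path` invisibly (write).
#' @export
write_optodes <- function(montage, path) {
  utils::write.csv(montage$optodes[, c("label", "tier", "x", "y", "z")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_optodes
#' @param surface a `scalp_surface` used to re-snap imported positions.
#' @export
read_optodes <- function(path, surface) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("label", "x", "y", "z") %in% names(df)))
  df$index <- surface_nearest(surface, as.matrix(df[, c("x", "y", "z")]))
  df$x <- surface$points[df$index, 1]
  df$y <- surface$points[df$index, 2]
  df$z <- surface$points[df$index, 3]
  if (is.null(df$tier)) df$tier <- "custom"
  df
}

#' Export a channel table as CSV
#'
#' @param channels a channel data frame.
#' @param path CSV path.
#' @export
write_channels <- function(channels, path) {
  utils::write.csv(channels, path, row.names = FALSE)
  invisible(path)
}
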