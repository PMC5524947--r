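# STAR particle-table reader/writer. Handles multi-block files (including a
# RELION >= 3.1 data_optics block), loop_ tables, both origin-shift dialects
# (legacy rlnOriginX/Y in pixels, rlnOriginXAngst/YAngst in Angstrom), and
# preserves columns it does not interpret.

## Parse every data_ block of a STAR file into a character data frame.
read_star_blocks <- function(path) {
  if (!file.exists(path)) stop("format error: file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)   # strip comments
  lines <- trimws(lines)
  blocks <- list()
  i <- 1L
  cur <- NULL
  while (i <= length(lines)) {
    ln <- lines[i]
    if (grepl("^data_", ln)) {
      cur <- sub("^data_", "", ln)
      i <- i + 1L
    } else if (ln == "loop_") {
      i <- i + 1L
      labels <- character()
      while (i <= length(lines) && grepl("^_", lines[i])) {
        labels <- c(labels, sub("\\s+.*$", "", sub("^_", "", lines[i])))
        i <- i + 1L
      }
      rows <- list()
      while (i <= length(lines) && nzchar(lines[i]) && !grepl("^(data_|loop_|_)", lines[i])) {
        fields <- strsplit(lines[i], "\\s+")[[1]]
        if (length(fields) != length(labels))
          stop("format error: row with ", length(fields), " fields for ",
               length(labels), " labels in ", path)
        rows[[length(rows) + 1L]] <- fields
        i <- i + 1L
      }
      df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
      names(df) <- labels
      blocks[[if (is.null(cur) || !nzchar(cur)) "data" else cur]] <- df
      cur <- NULL
    } else if (grepl("^_", ln)) {
      # key-value pair block (rare for particles); store as 1-row frame
      kv <- strsplit(ln, "\\s+")[[1]]
      nm <- if (is.null(cur) || !nzchar(cur)) "data" else cur
      if (is.null(blocks[[nm]])) blocks[[nm]] <- data.frame(row.names = 1)
      blocks[[nm]][[sub("^_", "", kv[1])]] <- kv[2]
      i <- i + 1L
    } else i <- i + 1L
  }
  if (!length(blocks)) stop("format error: no data blocks found in ", path)
  blocks
}

num <- function(x) suppressWarnings(as.numeric(x))

#' Read a STAR particle table
#'
#' Maps RELION-dialect columns onto the package's particle records: Euler
#' angles (rlnAngleRot/Tilt/Psi), origin shifts (rlnOriginX/Y in pixels or
#' rlnOriginXAngst/YAngst in Angstrom, auto-detected and converted), and CTF
#' parameters (defocus, voltage, Cs, amplitude contrast, phase shift). A
#' data_optics block, when present, supplies per-group pixel size, voltage,
#' Cs and amplitude contrast. Missing CTF columns give an identity CTF with
#' a warning; unknown columns are preserved and written back verbatim.
#'
#' @param path Path to the STAR file.
#' @param pixel_size Pixel size in Angstrom, used to convert Angstrom shifts
#'   when no optics block provides one.
#' @return Data frame of particle records: columns rot, tilt, psi, shift_x,
#'   shift_y (pixels), defocus_u, defocus_v, astig_angle, voltage, cs,
#'   amplitude_contrast, phase_shift, has_orientation, has_ctf, image_name,
#'   with unmapped columns kept in attribute \code{"extra"}.
#' @export
read_particles_star <- function(path, pixel_size = NULL) {
  blocks <- read_star_blocks(path)
  pb_name <- intersect(c("particles", "images", "data", names(blocks)[1]),
                       names(blocks))
  pb_name <- pb_name[!pb_name %in% "optics"][1]
  tab <- blocks[[pb_name]]
  optics <- blocks[["optics"]]

  get <- function(col) if (col %in% names(tab)) num(tab[[col]]) else NULL
  nr <- nrow(tab)

  # per-particle optics lookup
  opt <- function(col) {
    if (!is.null(optics) && col %in% names(optics)) {
      if ("rlnOpticsGroup" %in% names(tab) && "rlnOpticsGroup" %in% names(optics)) {
        idx <- match(tab$rlnOpticsGroup, optics$rlnOpticsGroup)
        num(optics[[col]])[idx]
      } else rep(num(optics[[col]])[1], nr)
    } else NULL
  }

  rot <- get("rlnAngleRot"); tilt <- get("rlnAngleTilt"); psi <- get("rlnAnglePsi")
  has_orientation <- !is.null(rot) && !is.null(tilt)
  if (!has_orientation) { rot <- rep(0, nr); tilt <- rep(0, nr) }
  if (is.null(psi)) psi <- rep(0, nr)

  px <- opt("rlnImagePixelSize")
  if (is.null(px)) px <- get("rlnImagePixelSize")
  if (is.null(px)) px <- get("rlnDetectorPixelSize")
  if (is.null(px) && !is.null(pixel_size)) px <- rep(pixel_size, nr)

  sx <- get("rlnOriginX"); sy <- get("rlnOriginY")
  if (is.null(sx) && "rlnOriginXAngst" %in% names(tab)) {
    if (is.null(px)) {
      warning("Angstrom-dialect shifts but no pixel size available; assuming 1 A/px")
      px <- rep(1, nr)
    }
    sx <- num(tab$rlnOriginXAngst) / px
    sy <- num(tab$rlnOriginYAngst) / px
  }
  if (is.null(sx)) sx <- rep(0, nr)
  if (is.null(sy)) sy <- rep(0, nr)

  du <- get("rlnDefocusU"); dv <- get("rlnDefocusV")
  has_ctf <- !is.null(du)
  if (!has_ctf) {
    warning("no CTF columns in ", basename(path), "; assuming identity CTF")
    du <- dv <- rep(0, nr)
  }
  if (is.null(dv)) dv <- du
  da <- get("rlnDefocusAngle"); if (is.null(da)) da <- rep(0, nr)
  kv <- opt("rlnVoltage"); if (is.null(kv)) kv <- get("rlnVoltage")
  if (is.null(kv)) kv <- rep(300, nr)
  cs <- opt("rlnSphericalAberration"); if (is.null(cs)) cs <- get("rlnSphericalAberration")
  if (is.null(cs)) cs <- rep(2.7, nr)
  ac <- opt("rlnAmplitudeContrast"); if (is.null(ac)) ac <- get("rlnAmplitudeContrast")
  if (is.null(ac)) ac <- rep(0.07, nr)
  ps <- get("rlnPhaseShift"); if (is.null(ps)) ps <- rep(0, nr)
  img <- if ("rlnImageName" %in% names(tab)) tab$rlnImageName else
    sprintf("%06d@stack.mrcs", seq_len(nr))

  rec <- data.frame(rot = rot, tilt = tilt, psi = psi,
                    shift_x = sx, shift_y = sy,
                    defocus_u = du, defocus_v = dv, astig_angle = da,
                    voltage = kv, cs = cs, amplitude_contrast = ac,
                    phase_shift = ps,
                    has_orientation = rep(has_orientation, nr),
                    has_ctf = rep(has_ctf, nr),
                    image_name = img, stringsAsFactors = FALSE)
  known <- c("rlnAngleRot", "rlnAngleTilt", "rlnAnglePsi", "rlnOriginX",
             "rlnOriginY", "rlnOriginXAngst", "rlnOriginYAngst",
             "rlnDefocusU", "rlnDefocusV", "rlnDefocusAngle", "rlnVoltage",
             "rlnSphericalAberration", "rlnAmplitudeContrast",
             "rlnPhaseShift", "rlnImageName")
  attr(rec, "extra") <- tab[setdiff(names(tab), known)]
  rec
}

fmt_star_num <- function(x) {
  ifelse(x == round(x), sprintf("%d", as.integer(round(x))), sprintf("%.6f", x))
}

#' Write particle records as a STAR table
#'
#' Writes a single \code{data_particles} loop with legacy pixel-unit origin
#' columns; any columns preserved by [read_particles_star()] (attribute
#' \code{"extra"}) are appended verbatim.
#'
#' @param records Particle record data frame (see [read_particles_star()]).
#' @param path Output path.
#' @param extra_cols Optional data frame of additional columns (e.g. scores)
#'   to append, one row per record.
#' @export
write_particles_star <- function(records, path, extra_cols = NULL) {
  cols <- list(rlnImageName = records$image_name,
               rlnAngleRot = fmt_star_num(records$rot),
               rlnAngleTilt = fmt_star_num(records$tilt),
               rlnAnglePsi = fmt_star_num(records$psi),
               rlnOriginX = fmt_star_num(records$shift_x),
               rlnOriginY = fmt_star_num(records$shift_y))
  if (any(records$has_ctf)) {
    cols <- c(cols, list(rlnDefocusU = fmt_star_num(records$defocus_u),
                         rlnDefocusV = fmt_star_num(records$defocus_v),
                         rlnDefocusAngle = fmt_star_num(records$astig_angle),
                         rlnVoltage = fmt_star_num(records$voltage),
                         rlnSphericalAberration = fmt_star_num(records$cs),
                         rlnAmplitudeContrast = fmt_star_num(records$amplitude_contrast),
                         rlnPhaseShift = fmt_star_num(records$phase_shift)))
  }
  ex <- attr(records, "extra")
  if (!is.null(ex) && ncol(ex) && nrow(ex) == nrow(records))
    for (nm in names(ex)) cols[[nm]] <- as.character(ex[[nm]])
  if (!is.null(extra_cols))
    for (nm in names(extra_cols)) cols[[nm]] <- fmt_star_num(extra_cols[[nm]])

  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("", "data_particles", "", "loop_",
               sprintf("_%s #%d", names(cols), seq_along(cols))), con)
  writeLines(do.call(paste, cols), con)
  invisible(path)
}
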