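#' @include trajectory-class.R
NULL

#' Atom-class map: chemical roles to atom selections
#'
#' Analysis stages never hard-code atom names; they ask the map for a role
#' (phosphate oxygens `Op`, carbonyl oxygens `Oc`, xanthophyll hydroxyl
#' `xan_OH_O`, ...).  Each role is a pair of character vectors: residue
#' names and atom names; `NULL` matches anything.  A shipped default covers
#' POPC / LUT / ZEA / 3-site water naming (primed xanthophyll atoms carry a
#' `P` suffix, e.g. `C3P` for C3').
#'
#' @slot roles named list; each element is `list(resname=, atoms=)`.
#' @export
setClass("AtomClassMap", representation(roles = "list"))

setValidity("AtomClassMap", function(object) {
  msgs <- character()
  if (is.null(names(object@roles)) || any(names(object@roles) == ""))
    msgs <- c(msgs, "all roles must be named")
  # chemically required disjointness of the PC oxygen classes
  oxy <- c("Op", "Oe", "Og", "Oc")
  present <- intersect(oxy, names(object@roles))
  if (length(present) > 1) {
    sets <- lapply(object@roles[present], function(r) r$atoms)
    for (i in seq_along(sets)) for (j in seq_len(i - 1L)) {
      ov <- intersect(sets[[i]], sets[[j]])
      if (length(ov))
        msgs <- c(msgs, paste0("roles ", present[j], " and ", present[i],
                               " share atoms: ", paste(ov, collapse = ",")))
    }
  }
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "AtomClassMap", function(object) {
  cat("AtomClassMap with", length(object@roles), "roles:\n ",
      paste(names(object@roles), collapse = " "), "\n")
})

.XAN_RESNAMES <- c("LUT", "ZEA", "XAN")

#' Default atom-class map for POPC / lutein / zeaxanthin / 3-site water
#'
#' Head-group oxygens follow the usual PC naming: non-esterified phosphate
#' O13/O14 (`Op`), esterified phosphate O11/O12 (`Oe`), glycerol O21/O31
#' (`Og`), carbonyl O22/O32 (`Oc`).  Xanthophyll primed atoms use a `P`
#' suffix.
#'
#' @return an [AtomClassMap].
#' @export
defaultClassMap <- function() {
  w_res <- c("SOL", "HOH", "TIP3", "WAT")
  roles <- list(
    P           = list(resname = "POPC", atoms = "P"),
    Op          = list(resname = "POPC", atoms = c("O13", "O14")),
    Oe          = list(resname = "POPC", atoms = c("O11", "O12")),
    Og          = list(resname = "POPC", atoms = c("O21", "O31")),
    Oc          = list(resname = "POPC", atoms = c("O22", "O32")),
    glycerol_O  = list(resname = "POPC", atoms = c("O21", "O31")),
    choline_N   = list(resname = "POPC", atoms = "N"),
    choline_CH3 = list(resname = "POPC", atoms = c("C13", "C14", "C15")),
    acyl_C      = list(resname = "POPC", atoms = c("C23", "C24", "C25",
                                                   "C33", "C34", "C35")),
    water_O     = list(resname = w_res, atoms = c("OW", "O", "OH2")),
    water_H     = list(resname = w_res, atoms = c("HW1", "HW2", "H1", "H2")),
    xan         = list(resname = .XAN_RESNAMES, atoms = NULL),
    C3          = list(resname = .XAN_RESNAMES, atoms = "C3"),
    C3prime     = list(resname = .XAN_RESNAMES, atoms = "C3P"),
    xan_OH_O    = list(resname = .XAN_RESNAMES, atoms = c("O3", "O3P")),
    xan_OH_H    = list(resname = .XAN_RESNAMES, atoms = c("H3O", "H3P")),
    ring_beta_atoms = list(resname = .XAN_RESNAMES,
                           atoms = c("C1", "C2", "C3", "C4", "C5", "C6")),
    ring_eps_atoms  = list(resname = .XAN_RESNAMES,
                           atoms = c("C1P", "C2P", "C3P", "C4P", "C5P", "C6P")),
    C13         = list(resname = .XAN_RESNAMES, atoms = "C13"),
    MET         = list(resname = .XAN_RESNAMES,
                       atoms = c("C19", "C20", "C19P", "C20P")),
    met_beta    = list(resname = .XAN_RESNAMES, atoms = c("C19", "C20")),
    met_eps     = list(resname = .XAN_RESNAMES, atoms = c("C19P", "C20P")),
    met_theta   = list(resname = .XAN_RESNAMES, atoms = "C20"),
    polyene_C   = list(resname = .XAN_RESNAMES,
                       atoms = c(paste0("C", 7:15), paste0("C", 7:15, "P")))
  )
  new("AtomClassMap", roles = roles)
}

#' Read an atom-class map from a YAML file
#'
#' The file maps role names to `resname:` / `atoms:` lists; roles absent
#' from the file fall back to the shipped default.
#'
#' @param path YAML file path.
#' @return an [AtomClassMap].
#' @export
readClassMap <- function(path) {
  if (!file.exists(path)) stop("class-map file not found: ", path)
  raw <- yaml::read_yaml(path)
  cm <- defaultClassMap()
  for (role in names(raw)) {
    r <- raw[[role]]
    cm@roles[[role]] <- list(
      resname = if (is.null(r$resname)) NULL else as.character(r$resname),
      atoms = if (is.null(r$atoms)) NULL else as.character(r$atoms))
  }
  methods::validObject(cm)
  cm
}

#' Write an atom-class map to YAML
#'
#' @param classmap an [AtomClassMap].
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
writeClassMap <- function(classmap, path) {
  yaml::write_yaml(classmap@roles, path)
  invisible(path)
}

#' Select atoms by role
#'
#' @param traj a [Trajectory].
#' @param classmap an [AtomClassMap].
#' @param role role name present in the map.
#' @param require error when the selection is empty (default FALSE).
#' @return integer vector of 1-based atom row indices.
#' @export
selectAtoms <- function(traj, classmap, role, require = FALSE) {
  r <- classmap@roles[[role]]
  if (is.null(r)) stop("unknown role: ", role)
  top <- atoms(traj)
  keep <- rep(TRUE, nrow(top))
  if (!is.null(r$resname)) keep <- keep & top$resname %in% r$resname
  if (!is.null(r$atoms)) keep <- keep & top$name %in% r$atoms
  idx <- which(keep)
  if (require && !length(idx))
    stop("required atom selection is empty for role '", role,
         "'; refusing to run this stage")
  idx
}

#' Xanthophyll molecules present in a trajectory
#'
#' @param traj a [Trajectory].
#' @param classmap an [AtomClassMap].
#' @return data.frame with columns `resname`, `resid`, `molecule_id`.
#' @export
xanMolecules <- function(traj, classmap) {
  idx <- selectAtoms(traj, classmap, "xan")
  if (!length(idx)) return(data.frame(resname = character(),
                                      resid = integer(),
                                      molecule_id = character()))
  top <- atoms(traj)[idx, ]
  u <- unique(top[, c("resname", "resid")])
  u <- u[order(u$resid), ]
  u$molecule_id <- paste0(u$resname, u$resid)
  rownames(u) <- NULL
  u
}

# atoms of one residue (resname+resid), optionally restricted to names
.residueAtoms <- function(traj, resname, resid, names = NULL) {
  top <- atoms(traj)
  keep <- top$resname == resname & top$resid == resid
  if (!is.null(names)) keep <- keep & top$name %in% names
  which(keep)
}
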