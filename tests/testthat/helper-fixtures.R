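# Shared fixture builders. Everything is generated in code at test time.

# Surface sample of a sphere (mm).
spherePoints <- function(r = 30, n = 3000, seed = 1) {
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    code
  }
  withr_seed({
    u <- stats::runif(n, -1, 1)
    th <- stats::runif(n, 0, 2 * pi)
    cbind(r * sqrt(1 - u^2) * cos(th), r * sqrt(1 - u^2) * sin(th), r * u)
  })
}

# Dense surface sample of an axis-aligned box (mm), spacing ~1 mm.
boxPoints <- function(hx = 10, hy = 15, hz = 20) {
  g <- expand.grid(
    x = seq(-hx, hx, by = 1), y = seq(-hy, hy, by = 1),
    z = seq(-hz, hz, by = 1)
  )
  on <- abs(abs(g$x) - hx) < 1e-9 | abs(abs(g$y) - hy) < 1e-9 | abs(abs(g$z) - hz) < 1e-9
  as.matrix(g[on, ])
}

# A tiny, fast, valid StructureSet (toy shapes, not anatomy).
toyStructureSet <- function(caseId = "toy") {
  structureSet(
    list(
      BRAIN_CTV = ellipsoidCloud(c(0, 0, 0), 60, 80, 55),
      EYE_L = ellipsoidCloud(c(31, -75, -35), 12, 12, 12),
      EYE_R = ellipsoidCloud(c(-31, -75, -35), 12, 12, 12),
      LENS_L = ellipsoidCloud(c(31, -83, -35), 4.5, 4.5, 4.5),
      LENS_R = ellipsoidCloud(c(-31, -83, -35), 4.5, 4.5, 4.5)
    ),
    isocenter = c(0, 0, 0), caseId = caseId
  )
}

ellipsoidCloud <- function(center, a, b, c) {
  autofif:::ellipsoidRings(center, a, b, c, dz = max(2, c / 6))
}

# Fake PlanResult with prescribed per-structure dose vectors.
fakePlan <- function(brain, eye = c(5, 6), lens = c(2, 3), prescription = 30) {
  methods::new("PlanResult",
    structureDose = list(
      BRAIN_CTV = brain, EYE_L = eye, EYE_R = eye + 0.5,
      LENS_L = lens, LENS_R = lens + 0.2
    ),
    voxelVolume = 0.008, spacing = 2,
    hyperparameters = autoFifHyperparameters(50, 2, 4, 6),
    prescription = prescription, seed = 1, engine = "test"
  )
}

# Independent sort-based oracle for Dx%: sort ascending, take the
# left-continuous interpolated order statistic at h = n * (1 - x/100)
# (the "largest d with >= x% of voxels >= d", linearly interpolated).
oracleDx <- function(doses, x) {
  v <- sort(doses)
  n <- length(v)
  h <- n * (1 - x / 100)
  if (h <= 1) {
    return(v[1])
  }
  k <- floor(h)
  if (k >= n) {
    return(v[n])
  }
  v[k] + (h - k) * (v[k + 1] - v[k])
}

# Wide-margin gaussian-cluster classification data for head tests.
separableData <- function(n = 40, k = 2, seed = 2) {
  set.seed(seed)
  X <- do.call(rbind, lapply(seq_len(k), function(cl) {
    matrix(stats::rnorm(n * 10, mean = 4 * cl, sd = 0.3), n, 10)
  }))
  colnames(X) <- paste0("f", 1:10)
  list(m = standardizeFeatures(featureMatrix(X)), y = rep(seq_len(k), each = n))
}

# A linear "head": f_k(x) = w_k . x, built for closed-form attribution tests.
linearHead <- function(W, id = "A") {
  methods::new("TrainedHead",
    id = id,
    spec = list(
      inputDim = nrow(W), hidden = integer(0), outDim = ncol(W),
      activations = character(0), dropout = numeric(0),
      lr = 1e-3, weightDecay = 0
    ),
    weights = list(list(W = W, b = rep(0, ncol(W)))),
    classes = headClasses(id),
    log = data.frame(), standardization = list()
  )
}

# Write a synthetic RTSTRUCT via the pre-installed pydicom (independent
# writer, so the reader is checked against a third-party encoder).
writeTestRTStruct <- function(path, mode = "ok") {
  script <- file.path(tempdir(), "make_rtstruct.py")
  if (!file.exists(script)) {
    writeLines(rtstructPySource(), script)
  }
  out <- suppressWarnings(system2("python", c(script, shQuote(path), mode),
    stdout = TRUE, stderr = TRUE
  ))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0) {
    stop("pydicom fixture generation failed: ", paste(out, collapse = "\n"))
  }
  path
}

rtstructPySource <- function() {
  c(
    "import sys",
    "from pydicom.dataset import Dataset, FileDataset",
    "from pydicom.uid import ExplicitVRLittleEndian, ImplicitVRLittleEndian, generate_uid",
    "",
    "def build(path, roi_specs, transfer='explicit'):",
    "    ts = ExplicitVRLittleEndian if transfer == 'explicit' else ImplicitVRLittleEndian",
    "    meta = Dataset()",
    "    meta.MediaStorageSOPClassUID = '1.2.840.10008.5.1.4.1.1.481.3'",
    "    meta.MediaStorageSOPInstanceUID = generate_uid()",
    "    meta.TransferSyntaxUID = ts",
    "    ds = FileDataset(path, {}, file_meta=meta, preamble=b'\\x00' * 128)",
    "    ds.is_little_endian = True",
    "    ds.is_implicit_VR = transfer != 'explicit'",
    "    ds.Modality = 'RTSTRUCT'",
    "    ds.SOPClassUID = meta.MediaStorageSOPClassUID",
    "    ds.SOPInstanceUID = meta.MediaStorageSOPInstanceUID",
    "    ds.PatientName = 'Test^Phantom'",
    "    ds.PatientID = 'TEST01'",
    "    ssr, rcs = [], []",
    "    for num, (name, contours) in enumerate(roi_specs, start=1):",
    "        item = Dataset()",
    "        item.ROINumber = num",
    "        item.ReferencedFrameOfReferenceUID = generate_uid()",
    "        item.ROIName = name",
    "        item.ROIGenerationAlgorithm = 'MANUAL'",
    "        ssr.append(item)",
    "        rc = Dataset()",
    "        rc.ReferencedROINumber = num",
    "        cseq = []",
    "        for pts in contours:",
    "            c = Dataset()",
    "            c.ContourGeometricType = 'CLOSED_PLANAR'",
    "            c.NumberOfContourPoints = len(pts) // 3",
    "            c.ContourData = ['%g' % v for v in pts]",
    "            cseq.append(c)",
    "        rc.ContourSequence = cseq",
    "        rcs.append(rc)",
    "    ds.StructureSetROISequence = ssr",
    "    ds.ROIContourSequence = rcs",
    "    ds.save_as(path, enforce_file_format=True)",
    "",
    "out, mode = sys.argv[1], sys.argv[2]",
    "def tri(z, dx=0.0):",
    "    return [10 + dx, 0, z, dx, 10, z, -10 + dx, -5, z]",
    "rois = [('Brain', [tri(0), tri(2)]), ('Eye_L', [tri(5, 30)]), ('Eye_R', [tri(6, -30)]),",
    "        ('Lens_L', [tri(7, 30)]), ('Lens_R', [tri(8, -30)])]",
    "if mode == 'missing':",
    "    rois = rois[:4]",
    "if mode == 'ambiguous':",
    "    rois = rois + [('brain_stem', [tri(9)])]",
    "build(out, rois, 'implicit' if mode == 'implicit' else 'explicit')"
  )
}

# Cache expensive shared objects across test files (per test_dir run).
.testCache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, envir = .testCache)) {
    assign(key, expr, envir = .testCache)
  }
  get(key, envir = .testCache)
}
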