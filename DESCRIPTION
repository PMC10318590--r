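Package: rowseg
Title: Row Selection and Plot Trimming for Plot-Level Remote Sensing Phenotyping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to evaluate row-segment selection and plot end trimming in
    multi-row field trials phenotyped by uncrewed aerial vehicles. Includes a
    synthetic field-trial generator with known genetic, replicate, border-row
    and alley effects; row-segment bounding-box construction and 40 cm end
    trimming; extraction of geometric traits (canopy cover, LiDAR canopy
    cover, 95th-percentile height, plot volume) and hyperspectral vegetation
    indices from point clouds and rasters; growing-degree-day phenology;
    entry-mean repeatability from restricted maximum likelihood variance
    components; repeated, subpopulation-balanced cross-validated support
    vector regression for end-season yield prediction; and factorial ANOVA
    with least-significant-difference letter groupings to compare row
    selections and trimming schemes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    jsonlite,
    kernlab,
    stats,
    utils,
    yaml
Suggests:
    lme4,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
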