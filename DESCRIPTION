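Package: methspan
Title: Linking Healthspan Traits, Liver DNA Methylation, and Mortality Risk in Mice
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-model analysis pipeline connecting longitudinal healthspan
    traits (food intake, body weight, body composition, fasting blood glucose),
    liver CpG methylation, and remaining lifespan in mice under chronic social
    stress. Model 1 maps standardized traits onto a methylation beta matrix by
    Moore-Penrose pseudoinverse multivariate regression, filters CpG sites by
    leave-one-out predictability (MAE/sigma), iteratively filters traits by
    inverse predictability (Spearman), and tests per-site trait associations by
    multiple linear regression with Benjamini-Hochberg adjustment. Model 2
    trains a multilayer perceptron on longitudinal records to predict weeks
    until death with animal-grouped cross-validation and ablation/scramble
    feature importance, transfers predictions to the methylation cohort via a
    weighted timepoint average, and selects aging-associated CpG sites by
    elastic-net regression. Cross-model CpG-set intersections are scored with a
    Monte-Carlo enrichment test. A seeded synthetic-data generator with planted
    trait-CpG and trait-lifespan effects makes every stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
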