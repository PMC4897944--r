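Package: clinsearch
Title: Progressive-Sampling Model Selection and Temporal Aggregation for Clinical Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated construction of clinical predictive models from
    entity-attribute-value (EAV) event data. Enumerates temporal aggregation
    periods and operators per clinical attribute and selects the most
    predictive pair per operator category by information gain; jointly
    searches learning algorithms, feature-selection techniques and
    hyper-parameter values by progressive sampling with a bagged-tree
    surrogate and expected-improvement proposals, eliminating unpromising
    algorithms and feature evaluators as the training sample doubles;
    predicts per-trial runtime to skip overly slow tests; builds a final
    ensemble by forward stepwise selection; and projects best-so-far model
    accuracy and expected patient outcome forward in time with weighted
    inverse-power-law learning curves. Includes synthetic EAV cohort and
    benchmark generators with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    rpart,
    randomForest,
    glmnet,
    e1071,
    class,
    xgboost,
    pROC
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
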