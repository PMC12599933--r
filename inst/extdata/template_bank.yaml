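# Template bank for the synthetic VTE radiology-report generator.
#
# Findings templates carry {slot} placeholders filled from `slots`; the
# first entry of each slot is its default wording, the rest are synonyms
# drawn with probability synonym_rate.  Negated findings appear only in the
# "No DVT or PE" bank and in the incidental_negatives of positive classes.
# The literal class label tokens never appear in any template (the "DVT"
# and "PE" abbreviations and the word "thrombophlebitis" are avoided), so
# rendered text cannot leak its own label.
headers:
  "chest CT":
    - "Contrast-enhanced CT of the chest."
    - "Chest CT with intravenous contrast."
  "pulmonary artery CT angiography":
    - "CT angiography of the pulmonary arteries."
    - "Pulmonary arterial phase CT angiogram."
  "lower extremity vein CT":
    - "CT venography of the lower extremities."
    - "Lower extremity venous phase CT."
  "DVT CT":
    - "Dedicated CT venography for suspected deep venous thrombosis."
    - "Indirect CT venography of the pelvis and lower extremities."
  "lower extremity vein duplex ultrasonography":
    - "Duplex ultrasonography of the lower extremity veins."
    - "Venous duplex examination of the lower extremities."
classes:
  "No DVT or PE":
    templates:
      - "No evidence of deep venous thrombus or pulmonary embolism."
      - "The imaged deep veins are patent with normal compressibility and no intraluminal thrombus."
      - "No filling defect to suggest thromboembolic disease within the imaged vessels."
      - "Patent deep venous system without thrombus; pulmonary arteries are unremarkable."
    incidental_negatives: []
  "PE only":
    templates:
      - "Filling defect {hedge} in the {lat} {pa_branch} pulmonary artery, consistent with acute embolism."
      - "An acute embolus {hedge} within the {lat} {pa_branch} pulmonary arterial branch."
      - "Acute thromboembolic occlusion of the {lat} {pa_branch} pulmonary artery {hedge}."
    incidental_negatives:
      - "The imaged deep veins of the lower extremities are patent."
  "Proximal DVT":
    templates:
      - "Occlusive thrombus {hedge} in the {lat} {prox_vein}."
      - "Echogenic intraluminal thrombus distends the {lat} {prox_vein} with absent color flow."
      - "Non-compressible {lat} {prox_vein} with an intraluminal filling defect {hedge}."
    incidental_negatives:
      - "No filling defect in the pulmonary arterial tree."
  "Distal DVT":
    templates:
      - "Thrombus {hedge} in the {lat} {dist_vein} below the knee."
      - "Echogenic material with absent flow in the {lat} {dist_vein}, involving the calf venous system."
      - "Non-compressible {lat} {dist_vein} consistent with calf venous thrombosis."
    incidental_negatives:
      - "The proximal deep veins are patent and compressible."
  "Thrombophlebitis":
    templates:
      - "Superficial thrombus {hedge} within the {lat} {saph_vein} with surrounding inflammatory change."
      - "The {lat} {saph_vein} is non-compressible with wall thickening, in keeping with superficial venous thrombosis."
      - "Partially occlusive superficial clot {hedge} in the {lat} {saph_vein}."
    incidental_negatives:
      - "The deep venous system is patent."
  "Other DVT":
    templates:
      - "Thrombus {hedge} in the {lat} {other_vein} of the upper venous system."
      - "Occlusive clot within the {lat} {other_vein}, an atypical site of venous thrombosis."
      - "Non-compressible {lat} {other_vein} with intraluminal echogenic thrombus {hedge}."
    incidental_negatives:
      - "No filling defect in the pulmonary arterial tree."
  "DVT and PE":
    # Compound class: rendered as one pulmonary-embolism sentence plus one
    # deep-vein sentence drawn from the banks below.
    pe_templates:
      - "Filling defect {hedge} in the {lat} {pa_branch} pulmonary artery, consistent with acute embolism."
      - "An acute embolus {hedge} within the {lat} {pa_branch} pulmonary arterial branch."
      - "Acute thromboembolic occlusion of the {lat} {pa_branch} pulmonary artery {hedge}."
    dvt_templates:
      - "Occlusive thrombus {hedge} in the {lat} {prox_vein}."
      - "Thrombus {hedge} in the {lat} {dist_vein} below the knee."
      - "Coexistent thrombus involving the {lat} {prox_vein}."
    incidental_negatives: []
distractors:
  - "Mild cardiomegaly."
  - "Trace right pleural effusion."
  - "Degenerative changes of the visualized spine."
  - "Bibasilar dependent atelectasis."
  - "Hepatic steatosis incidentally seen."
  - "Scattered atherosclerotic calcification of the aorta."
  - "Small hiatal hernia."
  - "Subcutaneous edema of the imaged soft tissues."
slots:
  hedge:
    - "is seen"
    - "is noted"
    - "is identified"
    - "is demonstrated"
  lat:
    - "right"
    - "left"
    - "bilateral"
  pa_branch:
    - "segmental"
    - "subsegmental"
    - "lobar"
    - "interlobar"
  prox_vein:
    - "femoral vein"
    - "popliteal vein"
    - "common femoral vein"
    - "external iliac vein"
    - "common iliac vein"
    - "inferior vena cava"
  dist_vein:
    - "soleal vein"
    - "peroneal vein"
    - "posterior tibial vein"
    - "gastrocnemius vein"
  saph_vein:
    - "great saphenous vein"
    - "small saphenous vein"
  other_vein:
    - "subclavian vein"
    - "internal jugular vein"
    - "axillary vein"
    - "brachial vein"
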