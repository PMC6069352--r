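# Default procedure/diagnosis code map (ILLUSTRATIVE).
#
# NCSP-style code stems for digestive-tract resections. National registry
# extractions use the full NOMESCO Classification of Surgical Procedures
# code list, which is not reproduced here; these stems exist so that the
# synthetic registry, tests and examples are self-contained. Replace with a
# site-specific map for real data.
#
# Each entry: code, organ (oesophageal | gastric | liver | pancreatoduodenal
# | distal_pancreatic | colonic | rectal), access (open | laparoscopic) and,
# for liver codes only, extent (major = three or more consecutive segments,
# Brisbane 2000; otherwise minor).
procedures:
  - {code: JCC20, organ: oesophageal, access: open}          # oesophageal resection
  - {code: JCC21, organ: oesophageal, access: laparoscopic}
  - {code: JDC30, organ: gastric, access: open}              # partial gastrectomy
  - {code: JDC31, organ: gastric, access: laparoscopic}
  - {code: JDD60, organ: gastric, access: open}              # total gastrectomy
  - {code: JDD61, organ: gastric, access: laparoscopic}
  - {code: JLC30, organ: pancreatoduodenal, access: open}    # pancreatoduodenectomy
  - {code: JLC31, organ: pancreatoduodenal, access: laparoscopic}
  - {code: JLC40, organ: distal_pancreatic, access: open}
  - {code: JLC41, organ: distal_pancreatic, access: laparoscopic}
  - {code: JJB50, organ: liver, access: open, extent: major} # hemihepatectomy class
  - {code: JJB51, organ: liver, access: laparoscopic, extent: major}
  - {code: JJB20, organ: liver, access: open, extent: minor} # segment/wedge class
  - {code: JJB21, organ: liver, access: laparoscopic, extent: minor}
  - {code: JFB30, organ: colonic, access: open}              # hemicolectomy
  - {code: JFB31, organ: colonic, access: laparoscopic}
  - {code: JFB40, organ: colonic, access: open}              # other colonic resection
  - {code: JFB41, organ: colonic, access: laparoscopic}
  - {code: JGB10, organ: rectal, access: open}               # rectal resection
  - {code: JGB11, organ: rectal, access: laparoscopic}

# Diagnosis-code prefixes accepted as colonic malignancy (ICD-10 style).
colonic_malignancy_patterns: [C18]
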