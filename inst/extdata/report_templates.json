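{
  "version": 1,
  "comment": "Sentence-template inventory for the synthetic neuroradiology report generator. Frames contain the placeholder {finding}. Negation frames keep the negating token at least three tokens away from the finding phrase (distant negation), and every bridge bigram immediately preceding {finding} also occurs in a positive frame, so the polarity of a mention is not recoverable from N-grams (N <= 3) local to the finding phrase.",
  "categories": {
    "acute_stroke": [
      "acute infarction in the left middle cerebral artery territory",
      "restricted diffusion consistent with acute ischaemia",
      "an acute ischaemic stroke",
      "acute cortical infarction with early swelling",
      "a small acute lacunar infarct"
    ],
    "mass": [
      "an enhancing mass lesion",
      "a space occupying lesion with surrounding oedema",
      "an extra axial mass",
      "a heterogeneous tumour in the posterior fossa",
      "a well defined enhancing lesion with mass effect"
    ],
    "atrophy": [
      "generalised cerebral volume loss in excess of age",
      "disproportionate hippocampal atrophy",
      "marked parenchymal atrophy",
      "focal volume loss in the temporal lobes",
      "progressive cortical atrophy"
    ],
    "vascular": [
      "a saccular aneurysm of the anterior communicating artery",
      "a vascular malformation",
      "scattered deep microhaemorrhages",
      "a dural arteriovenous fistula",
      "thrombosis of the transverse venous sinus"
    ],
    "small_vessel_disease": [
      "moderate chronic small vessel disease",
      "confluent periventricular small vessel change",
      "severe deep white matter small vessel disease",
      "extensive chronic microangiopathic change",
      "moderate to severe small vessel ischaemic change"
    ],
    "white_matter_inflammation": [
      "demyelinating lesions in a periventricular distribution",
      "active white matter inflammation",
      "inflammatory white matter lesions with enhancement",
      "multiple demyelinating plaques",
      "new inflammatory demyelination"
    ],
    "encephalomalacia": [
      "established encephalomalacia in the right frontal lobe",
      "chronic encephalomalacic change from previous infarction",
      "gliosis and encephalomalacia at the site of previous surgery",
      "mature cortical encephalomalacia",
      "post traumatic encephalomalacia with haemosiderin staining"
    ]
  },
  "benign_phrases": [
    "a normal intracranial study",
    "normal appearances for age",
    "preserved parenchymal volumes",
    "a structurally normal brain",
    "normal intracranial appearances"
  ],
  "positive_frames": [
    "appearances are strongly suggestive of {finding} .",
    "there is clear evidence of {finding} .",
    "the series demonstrates unequivocal features of {finding} .",
    "findings are in keeping with {finding} .",
    "the distribution is such as to suggest {finding} .",
    "the appearances do raise concern for {finding} ."
  ],
  "negation_frames": [
    "there are no features in either hemisphere suggestive of {finding} .",
    "no convincing imaging evidence of {finding} .",
    "the study does not demonstrate any definite features of {finding} .",
    "without any associated appearances in keeping with {finding} .",
    "nothing on the current study to suggest {finding} .",
    "insufficient appearances at this stage to raise concern for {finding} ."
  ],
  "hedge_frames": [
    "there may be some evidence of {finding} .",
    "appearances could be in keeping with {finding} .",
    "subtle change raising the possibility of early features of {finding} ."
  ],
  "normal_sentences": [
    "the ventricles and sulci are within normal limits for age .",
    "normal flow voids are demonstrated in the major intracranial vessels .",
    "the grey white matter differentiation is preserved .",
    "the posterior fossa structures are unremarkable .",
    "the pituitary and craniocervical junction are unremarkable .",
    "the orbits and paranasal sinuses are clear .",
    "midline structures are in a normal position ."
  ],
  "history_sentences": [
    "clinical history headache and visual disturbance .",
    "clinical history known multiple sclerosis for surveillance .",
    "clinical history previous fall with persistent dizziness .",
    "clinical history memory impairment under investigation .",
    "clinical history follow up of known intracranial pathology ."
  ],
  "protocol_sentences": [
    "imaging performed with axial t2 flair dwi and susceptibility weighted sequences .",
    "standard departmental protocol including post contrast volumetric t1 .",
    "limited protocol due to patient tolerance with axial t2 and dwi only ."
  ],
  "conclusion_sentences": [
    "conclusion as discussed above .",
    "conclusion findings discussed with the referring team .",
    "conclusion correlation with the clinical picture is advised .",
    "conclusion comparison with any prior external imaging would be helpful .",
    "conclusion report issued following review of all sequences ."
  ]
}
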