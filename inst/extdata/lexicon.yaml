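# Restriction-sentence lexicon: protection-level cues, body-part keywords,
# laterality markers, process-only keywords and canonical rendering
# templates. Portuguese is the language the profiles are written in;
# English mirrors are provided because worked examples print in English.
# Edit or extend this file to adapt the extractor to a local vocabulary;
# unknown body words are reported by the extractor, never guessed.
languages:
  en:
    levels:
      MN: ["must not"]
      SN: ["should not"]
    frame: "{cue} perform tasks that {body}."
    frame_level_end: "Perform tasks that {body} - {cue}."
    regions:
      neck: [neck]
      trunk: [trunk]
      shoulder: [shoulder, shoulders]
      elbow: [elbow, elbows]
      wrist: [wrist, wrists]
      fingers: [finger, fingers]
      knee: [knee, knees]
      foot: [foot, feet]
    laterality:
      left: [left]
      right: [right]
      both: [both]
    connectors: [and, or]
    process_keywords: [vibration, "manual material handling"]
    body_phrases:
      neck:
        none: "involve movements of the neck"
      trunk:
        none: "involve performing flexion rotation movements of the trunk"
      shoulder:
        both: "involve movements above both shoulders"
        L: "involve movements above the left shoulder"
        R: "involve movements above the right shoulder"
      elbow:
        both: "involve movements of both elbows"
        L: "involve movements of the left elbow"
        R: "involve movements of the right elbow"
      wrist:
        both: "involve movements of both wrists"
        L: "involve rotation movements of the left wrist"
        R: "involve rotation movements of the right wrist"
      fingers:
        both: "require force with fingers of both hands"
        L: "require force with fingers of the left hand"
        R: "require force with fingers of the right hand"
      knee:
        both: "involve flexion of both knees"
        L: "involve flexion of the left knee"
        R: "involve flexion of the right knee"
      foot:
        both: "involve repeated pressure with both feet"
        L: "involve repeated pressure with the left foot"
        R: "involve repeated pressure with the right foot"
    process_phrases:
      vibration: "imply performing tasks using tools with associated vibration"
      manual_material_handling: "involve manual material handling"
  pt:
    levels:
      MN: ["não pode", "nao pode"]
      SN: ["não deve", "nao deve"]
    frame: "{cue} executar tarefas que {body}."
    frame_level_end: "Executar tarefas que {body} - {cue}."
    regions:
      neck: [pescoço, pescoco]
      trunk: [tronco]
      shoulder: [ombro, ombros]
      elbow: [cotovelo, cotovelos]
      wrist: [punho, punhos]
      fingers: [dedo, dedos]
      knee: [joelho, joelhos]
      foot: [pé, pe, pés, pes]
    laterality:
      left: [esquerdo, esquerda, esquerdos, esquerdas]
      right: [direito, direita, direitos, direitas]
      both: [ambos, ambas]
    connectors: [e, ou]
    process_keywords: [vibração, vibracao, "movimentação manual de cargas", "movimentacao manual de cargas"]
    body_phrases:
      neck:
        none: "impliquem movimentos do pescoço"
      trunk:
        none: "impliquem movimentos de flexão e rotação do tronco"
      shoulder:
        both: "impliquem movimentos acima de ambos os ombros"
        L: "impliquem movimentos acima do ombro esquerdo"
        R: "impliquem movimentos acima do ombro direito"
      elbow:
        both: "impliquem movimentos de ambos os cotovelos"
        L: "impliquem movimentos do cotovelo esquerdo"
        R: "impliquem movimentos do cotovelo direito"
      wrist:
        both: "impliquem movimentos de ambos os punhos"
        L: "impliquem movimentos de rotação do punho esquerdo"
        R: "impliquem movimentos de rotação do punho direito"
      fingers:
        both: "exijam força com os dedos de ambas as mãos"
        L: "exijam força com os dedos da mão esquerda"
        R: "exijam força com os dedos da mão direita"
      knee:
        both: "impliquem flexão de ambos os joelhos"
        L: "impliquem flexão do joelho esquerdo"
        R: "impliquem flexão do joelho direito"
      foot:
        both: "impliquem pressão repetida com ambos os pés"
        L: "impliquem pressão repetida com o pé esquerdo"
        R: "impliquem pressão repetida com o pé direito"
    process_phrases:
      vibration: "impliquem utilizar ferramentas com vibração associada"
      manual_material_handling: "impliquem movimentação manual de cargas"
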