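# Severity lexicon for echo-report conclusions (editable; validated at load).
# Patterns are case-insensitive PCRE; "(?-i:AS)" keeps the abbreviation
# case-sensitive so prose "as" never matches. Negation uses forward scoping:
# a cue negates matches within scope_window tokens, stopping at . ; :
# This lexicon is a reconstruction for native-valve transthoracic reports;
# site-specific phrasing is expected to vary, so ship your own copy.
scope_window: 6
negation_cues:
  - "\\bno\\b"
  - "\\bnot\\b"
  - "\\bwithout\\b"
  - "\\babsence of\\b"
  - "\\bfree of\\b"
  - "\\bnegative for\\b"
  - "\\brather than\\b"
severity:
  - {id: sev_critical_full, pattern: "\\bcritical aortic( valve)? stenosis\\b", grade: critical, priority: 14}
  - {id: sev_critical_abbr, pattern: "\\bcritical \\b(?-i:AS)\\b", grade: critical, priority: 13}
  - {id: sev_modsev_full, pattern: "\\bmoderate[ -](to[ -])?severe aortic( valve)? stenosis\\b", grade: moderate_to_severe, priority: 12}
  - {id: sev_modsev_abbr, pattern: "\\bmoderate[ -](to[ -])?severe \\b(?-i:AS)\\b", grade: moderate_to_severe, priority: 11}
  - {id: sev_severe_full, pattern: "\\bsevere aortic( valve)? stenosis\\b", grade: severe, priority: 10}
  - {id: sev_severe_abbr, pattern: "\\bsevere \\b(?-i:AS)\\b", grade: severe, priority: 9}
  - {id: sev_mildmod_full, pattern: "\\bmild[ -](to[ -])?moderate aortic( valve)? stenosis\\b", grade: mild_to_moderate, priority: 8}
  - {id: sev_mildmod_abbr, pattern: "\\bmild[ -](to[ -])?moderate \\b(?-i:AS)\\b", grade: mild_to_moderate, priority: 7}
  - {id: sev_moderate_full, pattern: "\\bmoderate aortic( valve)? stenosis\\b", grade: moderate, priority: 6}
  - {id: sev_moderate_abbr, pattern: "\\bmoderate \\b(?-i:AS)\\b", grade: moderate, priority: 5}
  - {id: sev_mild_full, pattern: "\\bmild aortic( valve)? stenosis\\b", grade: mild, priority: 4}
  - {id: sev_mild_abbr, pattern: "\\bmild \\b(?-i:AS)\\b", grade: mild, priority: 3}
generic_as:
  - "\\baortic( valve)? stenosis\\b"
  - "\\bstenosis\\b"
  - "\\b(?-i:AS)\\b"
leaflet_restriction:
  - "\\brestricted[a-z ,]{0,30}\\bleaflet"
  - "\\bleaflet[a-z ,]{0,20}\\brestrict"
  - "\\brestricted (systolic )?(leaflet )?excursion\\b"
  - "\\breduced leaflet (excursion|mobility)\\b"
abnormal_gradient:
  - "\\b(elevated|increased|abnormal|abnormally high|high) (trans(aortic|valvular) )?(mean |peak )?gradient"
prosthetic:
  - "\\bprosthe"
  - "\\bbioprosthe"
  - "\\bmechanical (aortic )?valve\\b"
  - "\\b(?-i:TAVR)\\b"
  - "\\b(?-i:SAVR)\\b"
  - "\\b(?-i:AVR)\\b"
  - "\\b(aortic )?valve replacement\\b"
  - "\\bs/p (aortic )?valve (replacement|repair)\\b"
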