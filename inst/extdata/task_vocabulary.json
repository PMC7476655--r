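{
  "note": "SYNTHETIC RECONSTRUCTION: the questionnaire/bespoke split and the adapted-item flags are provisional; the study did not publish the adapted wording. snapshot_pct / participant_pct are the published ranking shares, usable as default task probabilities for simulation.",
  "task_label": ["Find something on a crowded shelf", "Use appliance dials, buttons, and remotes", "Read signs", "Read package labels", "Use PC", "Prepare meals", "Use public transportation", "Get around outdoors in places you know", "Read mail and cards", "Watch TV", "Read newspaper or magazine articles", "Avoid bumping into things and tripping", "Cross street", "Do yard work, DIY, and maintenance", "Fix a snack or a drink", "Groom yourself", "Clean the house and other household chores", "Read notices", "Read documents", "Read menus", "Read street signs and store names", "Match clothes", "Get around indoors in places you know", "Identify medicine", "Go down/up steps", "Read books", "See photographs", "Work on your favorite hobby", "Read timetables", "Go to the movies", "Read maps", "Read newspaper and magazine headlines", "Identify money", "Tell time", "Play sports and exercise", "Read recipes", "Recognize people from across the room", "Handle finances", "Physically get dressed", "Get around in unfamiliar places", "Play table and card games", "Eat and drink neatly", "Go out at night", "Find public restrooms", "Recognize people up close", "Sign your name", "Identify food on a plate", "Adjust to light changes", "Appreciate environment", "Search visually", "Other", "Use portable electronic devices", "ATM and other self-service machines", "Read other", "Read print on TV", "Read writing"],
  "is_bespoke": [false, false, false, false, false, false, false, false, false, false, false, false, false, false, false, false, false, false, false, false, false, false, false, false, false, false, false, false, false, false, false, false, false, false, false, false, false, false, false, false, false, false, false, false, false, false, false, false, true, true, true, true, true, true, true, true],
  "adapted": [true, true, false, true, true, false, true, false, false, true, false, false, false, false, false, false, false, false, false, false, false, true, false, true, false, false, true, false, true, false, false, false, false, true, false, true, false, false, false, false, false, false, false, false, false, false, false, false, false, false, false, false, false, false, false, false],
  "snapshot_pct": [8, 8, 7, 5, 5, 3, 3, 3, 2, 2, 2, 2, 2, 2, 2, 2, 2, 2, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 0.5, 0.5, 0.5, 0.5, 0.3, 0.3, 0.3, 0.3, 0.2, 0.2, 0.2, 0.2, 3, 3, 3, 3, 1, 1, 2, 0.5],
  "participant_pct": [59, 59, 53, 59, 38, 16, 28, 22, 38, 44, 34, 19, 25, 16, 16, 19, 13, 19, 25, 22, 25, 19, 19, 16, 13, 22, 13, 16, 19, 3, 13, 9, 9, 13, 6, 13, 9, 3, 3, 3, 3, 3, 6, 6, 3, 3, 3, 3, 25, 25, 19, 31, 22, 22, 25, 6]
}
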