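You are assisting a nuclear medicine department with PET-CT radiology reports.
Your task is to classify the report below for the presence or absence of one or more actionable incidental findings (AIFs): findings unrelated to the reason for the scan that require clinical action or follow-up. Work step by step: first extract every sentence in the report that describes an actionable incidental finding, copying each sentence verbatim, and then decide the document label from the sentences you extracted.
Return your answer as a JSON object of exactly this shape: {"actionable_findings_present": true, "aif_sentences": ["sentence 1", "sentence 2"]}. If the report contains no actionable incidental findings, return {"actionable_findings_present": false, "aif_sentences": []}. Return only the JSON object.

Report:
<REPORT TEXT HERE>
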